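## Readers/writers for the standard formats the tool touches. FASTA goes
## through Biostrings; alignments come in as a minimal SAM dialect (primary,
## paired, strand, optional NH hit-count tag) or as an equivalent TSV that
## needs no alignment toolchain at all; scaffolds go out as FASTA + AGP v2.1.

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of upper-case sequences, in file order.
#'   Duplicate identifiers are an error.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate FASTA ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(ss) && any(Biostrings::width(ss) == 0L)) stop("empty sequence in ", path)
  setNames(toupper(as.character(ss)), ids)
}

#' Write a FASTA file
#'
#' @param records Named character vector of sequences (or a `DNAStringSet`).
#' @param path Output path.
#' @param wrap Line width, default 60.
#' @return `path`, invisibly. `read_fasta(write_fasta(x))` round-trips.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  if (inherits(records, "XStringSet")) records <- setNames(as.character(records), names(records))
  if (length(records) && (is.null(names(records)) || anyDuplicated(names(records)) ||
                          any(!nzchar(names(records)))))
    stop("records must have unique, non-empty names")
  ss <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(ss, path, width = max(1L, as.integer(wrap)))
  invisible(path)
}

## reference span consumed by a CIGAR string (M/D/N/=/X advance the reference)
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(NA_real_)
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.numeric(sub("[A-Z=]$", "", toks))
    op <- sub("^\\d+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read paired-read alignments
#'
#' Parses alignments into the canonical placement table. Two formats:
#'
#' * `"sam"`: a minimal SAM dialect. Mandatory 11 columns; `@SQ` header
#'   lines are required (reference lengths are used to bound-check
#'   coordinates). FLAG bits honoured: 0x1 paired, 0x4 unmapped (skipped),
#'   0x10 strand, 0x40/0x80 first/second mate, 0x100 secondary (skipped),
#'   0x800 supplementary (skipped). `n_hits` is taken from an `NH:i:` tag
#'   when present, otherwise from the number of mapped records per read.
#' * `"tsv"`: tab-separated with columns `pair_id`, `mate`, `scaffold`,
#'   `start`, `end`, `strand`, `n_hits` (0-based half-open); works with no
#'   alignment toolchain installed.
#'
#' @param path Input file.
#' @param format `"sam"` or `"tsv"`; default guessed from the extension.
#' @return A placement table ([placement_table()]), one row per primary
#'   mapped alignment.
#' @export
read_alignments <- function(path, format = c("auto", "sam", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "tsv"
  if (format == "tsv") {
    dt <- fread(path, sep = "\t", header = TRUE,
                colClasses = list(character = c("pair_id", "scaffold", "strand")))
    return(placement_table(dt$pair_id, dt$mate, dt$scaffold, dt$start, dt$end,
                           dt$strand, dt$n_hits))
  }
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  if (!length(sq)) stop("SAM input lacks @SQ header lines")
  ref_len <- setNames(
    as.numeric(sub("^.*\tLN:([0-9]+).*$", "\\1", sq)),
    sub("^.*\tSN:([^\t]+).*$", "\\1", sq)
  )
  if (!length(body))
    return(placement_table(character(), integer(), character(), numeric(),
                           numeric(), character()))
  f <- tstrsplit(body, "\t", fill = NA_character_)
  if (length(f) < 11L) stop("SAM lines must have at least 11 fields")
  flag <- as.integer(f[[2]])
  qname <- f[[1]]
  mapped <- bitwAnd(flag, 0x4) == 0L
  keep <- mapped & bitwAnd(flag, 0x100) == 0L & bitwAnd(flag, 0x800) == 0L
  mate_idx <- fifelse(bitwAnd(flag, 0x80) > 0L, 2L, 1L)
  ## NH tag from optional fields
  nh <- rep(NA_integer_, length(body))
  if (length(f) > 11L) {
    opt <- do.call(paste, c(f[12:length(f)], sep = "\t"))
    m <- regmatches(opt, regexpr("NH:i:\\d+", opt))
    has <- regexpr("NH:i:\\d+", opt) > 0
    nh[has] <- as.integer(sub("NH:i:", "", m))
  }
  pos <- as.numeric(f[[4]])
  spanr <- cigar_ref_span(f[[6]])
  rname <- f[[3]]
  ## mapped-record count per (read, mate) as the fallback hit count
  ## (secondary records count towards multi-mapping)
  cnt_dt <- data.table(qname = qname[mapped], mate = mate_idx[mapped])
  cnt_dt <- cnt_dt[, .N, by = .(qname, mate)]
  dt <- data.table(qname = qname, flag = flag, rname = rname, pos = pos,
                   span = spanr, mate = mate_idx, nh = nh)[keep]
  dt[cnt_dt, n_rec := i.N, on = c(qname = "qname", mate = "mate")]
  dt[, n_hits := fifelse(is.na(nh), n_rec, pmax(nh, n_rec))]
  if (anyNA(dt$span)) stop("primary alignment with '*' CIGAR")
  len <- ref_len[dt$rname]
  if (anyNA(len)) stop("alignment to sequence absent from @SQ header")
  if (any(dt$pos - 1 + dt$span > len)) stop("alignment beyond declared reference length")
  placement_table(dt$qname, dt$mate, dt$rname, dt$pos - 1, dt$pos - 1 + dt$span,
                  fifelse(bitwAnd(dt$flag, 0x10) > 0L, "-", "+"), dt$n_hits,
                  read_id = paste0(dt$qname, "/", dt$mate))
}

#' Write a placement table as alignment TSV
#'
#' @param placements A placement table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(placements, path) {
  fwrite(placements[, .(pair_id, mate, scaffold, start, end, strand, n_hits)],
         path, sep = "\t")
  invisible(path)
}

#' Write scaffold paths as AGP v2.1
#'
#' Encodes ordered, oriented contig chains as AGP v2.1: alternating `W`
#' (component) and `N` (gap) rows, 1-based inclusive coordinates, gap rows
#' with gap_type `scaffold`, linkage `yes`, evidence `paired-ends`.
#'
#' @param paths A scaffold-path table (columns `object`, `contig`, `orient`,
#'   `gap_after`; `gap_after` is `NA` on the last component of each object).
#' @param contig_lengths Named numeric vector of component lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(paths, contig_lengths, path) {
  unknown <- setdiff(paths$contig, names(contig_lengths))
  if (length(unknown)) stop("unknown contig in paths: ", paste(unknown, collapse = ", "))
  bad_gap <- !is.na(paths$gap_after) & paths$gap_after <= 0
  if (any(bad_gap)) stop("non-positive gap length in paths")
  rows <- vector("list", nrow(paths) * 2L)
  k <- 0L
  for (obj in unique(paths$object)) {
    p <- paths[paths$object == obj, ]
    at <- 0; part <- 0L
    for (i in seq_len(nrow(p))) {
      len <- contig_lengths[[p$contig[i]]]
      part <- part + 1L; k <- k + 1L
      rows[[k]] <- sprintf("%s\t%.0f\t%.0f\t%d\tW\t%s\t1\t%.0f\t%s",
                           obj, at + 1, at + len, part, p$contig[i], len, p$orient[i])
      at <- at + len
      if (i < nrow(p)) {
        g <- p$gap_after[i]
        part <- part + 1L; k <- k + 1L
        rows[[k]] <- sprintf("%s\t%.0f\t%.0f\t%d\tN\t%.0f\tscaffold\tyes\tpaired-ends",
                             obj, at + 1, at + g, part, g)
        at <- at + g
      }
    }
  }
  writeLines(c("##agp-version\t2.1", unlist(rows[seq_len(k)])), path)
  invisible(path)
}

#' Read an AGP v2.1 file back into a scaffold-path table
#'
#' @param path AGP file written by [write_agp()] (W and N rows).
#' @return A scaffold-path table (columns `object`, `contig`, `orient`,
#'   `gap_after`).
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- tstrsplit(lines, "\t", fill = NA_character_)
  dt <- data.table(object = f[[1]], type = f[[5]], col6 = f[[6]], col9 = f[[9]])
  w <- dt$type == "W"
  out <- dt[w, .(object, contig = col6, orient = col9)]
  ## attach each N row's length to the preceding W row
  gap_after <- rep(NA_real_, sum(w))
  wi <- cumsum(w)             # index of the W row each line follows
  nrows <- which(dt$type == "N")
  gap_after[wi[nrows]] <- as.numeric(dt$col6[nrows])
  out[, gap_after := gap_after]
  out[]
}

#' Reconstruct scaffold sequences from AGP + component sequences
#'
#' @param agp A scaffold-path table (as from [read_agp()]).
#' @param contigs Named character vector of component sequences.
#' @return Named character vector of scaffold sequences ('-' components
#'   reverse-complemented, gaps rendered as `N` runs).
#' @export
agp_to_fasta <- function(agp, contigs) {
  vapply(split(agp, by = "object", sorted = FALSE), function(p) {
    pieces <- character(0)
    for (i in seq_len(nrow(p))) {
      s <- contigs[[p$contig[i]]]
      if (is.null(s)) stop("missing contig sequence: ", p$contig[i])
      if (p$orient[i] == "-") s <- revcomp(s)
      pieces <- c(pieces, s)
      if (!is.na(p$gap_after[i]))
        pieces <- c(pieces, strrep("N", p$gap_after[i]))
    }
    paste(pieces, collapse = "")
  }, character(1))
}

#' Write a discrepancy table as a BED-like TSV
#'
#' Columns: `scaffold`, `start`, `end` (0-based half-open), `kind`,
#' `support`, `median_span`. Output is sorted by (scaffold, start, end,
#' kind), so it is stable under permutation of the input.
#'
#' @param discrepancies A discrepancy table (see [classify_windows()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_discrepancies <- function(discrepancies, path) {
  cols <- c("scaffold", "start", "end", "kind", "support", "median_span")
  d <- as.data.table(discrepancies)
  if (!nrow(d)) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  d <- d[, ..cols][order(scaffold, start, end, kind)]
  fwrite(d, path, sep = "\t")
  invisible(path)
}
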