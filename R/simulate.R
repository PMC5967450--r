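## Synthetic fixtures with known ground truth. A genome with interspersed
## repeat families is turned into an "assembly" by fragmenting it and
## injecting structural errors; the edit history is kept as a block map
## (assembly intervals -> genome source intervals + strand), so simulated
## mate pairs are drawn on the TRUE genome and projected through the map
## onto the flawed assembly. Pairs spanning an injected error then produce
## exactly the discordant signal the assessment engine is meant to detect,
## with no external aligner in the loop.

#' Generate a random genome with interspersed repeat families
#'
#' Uniform random background at the requested GC content, with
#' `n_families` repeat families of `copies` copies each interspersed at
#' random non-overlapping positions. Each copy is independently mutated at
#' 2% of its positions (>= 95% identity within a family), which is what
#' makes repeat-derived reads multi-map.
#'
#' @param length Genome length in bp (default 10 Mb).
#' @param n_families Number of repeat families (default 5).
#' @param copies Copies per family (default 20).
#' @param unit_bp Repeat unit length (default 5,000).
#' @param gc GC fraction of the background (default 0.46).
#' @param seed Random seed (default 42).
#' @return An object of class `ml_genome`: `id`, `seq`, `length`,
#'   `repeats` (data.table: `family`, `copy`, `start`, `end`, `copies`),
#'   `gc`.
#' @export
sim_genome <- function(length = 1e7, n_families = 5L, copies = 20L, unit_bp = 5000L,
                       gc = 0.46, seed = 42L) {
  stopifnot(length >= 1, gc > 0, gc < 1)
  n_rep <- n_families * copies
  if (n_rep * unit_bp > 0.5 * length)
    stop("repeats would occupy more than half the genome")
  set.seed(seed)
  alph <- c("A", "C", "G", "T")
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seq_v <- sample(alph, length, replace = TRUE, prob = prob)
  repeats <- data.table(family = integer(), copy = integer(), start = numeric(),
                        end = numeric(), copies = integer())
  if (n_rep > 0L) {
    ## non-overlapping random placements, >= 1 kb apart: draw unordered
    ## positions in the slack left after reserving every (unit + spacer)
    ## footprint, then stack the footprints back on
    foot <- unit_bp + 1000
    slack <- length - n_rep * foot
    starts <- sort(floor(runif(n_rep, 0, slack))) + foot * (seq_len(n_rep) - 1L)
    units <- replicate(n_families,
                       sample(alph, unit_bp, replace = TRUE, prob = prob),
                       simplify = FALSE)
    fam <- rep(seq_len(n_families), each = copies)
    for (i in seq_len(n_rep)) {
      u <- units[[fam[i]]]
      nmut <- round(0.02 * unit_bp)
      if (nmut > 0L) {
        at <- sample.int(unit_bp, nmut)
        u[at] <- sample(alph, nmut, replace = TRUE)
      }
      seq_v[(starts[i] + 1):(starts[i] + unit_bp)] <- u
    }
    repeats <- data.table(family = fam, copy = rep(seq_len(copies), n_families),
                          start = starts, end = starts + unit_bp,
                          copies = as.integer(copies))
  }
  structure(list(id = "sim_genome", seq = paste(seq_v, collapse = ""),
                 length = as.numeric(length), repeats = repeats, gc = gc),
            class = "ml_genome")
}

#' @export
print.ml_genome <- function(x, ...) {
  cat(sprintf("<ml_genome> %.1f Mb, %d repeat copies, GC target %.2f\n",
              x$length / 1e6, nrow(x$repeats), x$gc))
  invisible(x)
}

## locate the pristine ('+', untagged, non-marker) block containing genome
## interval [s, e); returns its row index in `blocks`
find_block <- function(blocks, s, e) {
  i <- which(blocks$src_start <= s & blocks$src_end >= e & blocks$strand == "+" &
               is.na(blocks$tag) & blocks$src_end > blocks$src_start)
  if (length(i) != 1L)
    stop(sprintf("error coordinates [%d, %d) do not fall in a single unmodified region", s, e))
  i
}

## replace block row i by the given replacement rows (same scaffold)
splice_blocks <- function(blocks, i, repl) {
  rbind(if (i > 1L) blocks[seq_len(i - 1L)],
        repl,
        if (i < nrow(blocks)) blocks[(i + 1L):nrow(blocks)])
}

#' Derive an assembly from a genome by fragmentation and error injection
#'
#' Cuts the genome into scaffolds at `fragments` (recording the true
#' adjacencies) and applies structural errors in order. Supported kinds:
#'
#' * `deletion`: drop `[start, start+size)` from the assembly;
#' * `insertion`: duplicate `[start, start+size)` in place (the assembly
#'   carries an extra copy);
#' * `inversion`: reverse-complement `[start, start+size)`;
#' * `misjoin`: chimeric tail swap -- the scaffold regions containing
#'   `start` and `start2` exchange everything downstream of those points,
#'   creating one chimeric junction in each scaffold.
#'
#' Error coordinates are genome coordinates and must fall in regions not
#' touched by earlier edits.
#'
#' @param genome An `ml_genome`.
#' @param errors `NULL`, or a data.table/data.frame with columns `kind`,
#'   `start`, `size` (`NA` for misjoin) and `start2` (misjoin only).
#' @param fragments Numeric vector of genome cut positions (0 < pos <
#'   genome length); empty for a single-scaffold assembly.
#' @return An object of class `ml_assembly`: `records` (named character
#'   vector), `lengths`, `blocks` (the assembly->genome map), `truth`
#'   (data.table: `kind`, `scaffold`, `start`, `end`, `size` on assembly
#'   coordinates), `adjacency` (data.table: `a_id`, `b_id` of true
#'   neighbours, genome order, both `+`).
#' @export
inject_errors <- function(genome, errors = NULL, fragments = numeric(0)) {
  stopifnot(inherits(genome, "ml_genome"))
  fragments <- sort(unique(as.numeric(fragments)))
  if (length(fragments) && (min(fragments) <= 0 || max(fragments) >= genome$length))
    stop("fragment positions must lie strictly inside the genome")
  bounds <- c(0, fragments, genome$length)
  n_scf <- length(bounds) - 1L
  ids <- sprintf("scf_%03d", seq_len(n_scf))
  blocks <- data.table(scaffold = ids, src_start = bounds[-length(bounds)],
                       src_end = bounds[-1], strand = "+", tag = NA_character_)
  adjacency <- if (n_scf > 1L)
    data.table(a_id = ids[-n_scf], b_id = ids[-1]) else
    data.table(a_id = character(), b_id = character())
  truth_meta <- list()
  if (!is.null(errors) && nrow(errors)) {
    errors <- as.data.table(errors)
    if (!"start2" %in% names(errors)) errors[, start2 := NA_real_]
    for (k in seq_len(nrow(errors))) {
      kind <- errors$kind[k]; s <- errors$start[k]; sz <- errors$size[k]
      if (kind %in% c("deletion", "insertion", "inversion")) {
        if (!is.finite(sz) || sz <= 0) stop("size must be positive for ", kind)
        i <- find_block(blocks, s, s + sz)
        b <- blocks[i]
        pre <- data.table(scaffold = b$scaffold, src_start = b$src_start, src_end = s,
                          strand = "+", tag = NA_character_)
        post <- data.table(scaffold = b$scaffold, src_start = s + sz, src_end = b$src_end,
                           strand = "+", tag = NA_character_)
        tag <- sprintf("%s_%d", kind, k)
        repl <- switch(kind,
          deletion = rbind(pre,
                           data.table(scaffold = b$scaffold, src_start = s, src_end = s,
                                      strand = "+", tag = tag),   # zero-width marker
                           post),
          insertion = rbind(pre,
                            data.table(scaffold = b$scaffold, src_start = s, src_end = s + sz,
                                       strand = "+", tag = NA_character_),
                            data.table(scaffold = b$scaffold, src_start = s, src_end = s + sz,
                                       strand = "+", tag = tag),
                            post),
          inversion = rbind(pre,
                            data.table(scaffold = b$scaffold, src_start = s, src_end = s + sz,
                                       strand = "-", tag = tag),
                            post)
        )
        blocks <- splice_blocks(blocks, i, repl)
        truth_meta[[k]] <- data.table(kind = kind, tag = tag, size = sz)
      } else if (kind == "misjoin") {
        s2 <- errors$start2[k]
        if (!is.finite(s2)) stop("misjoin needs 'start2'")
        ia <- find_block(blocks, s, s)
        ib <- find_block(blocks, s2, s2)
        a_scf <- blocks$scaffold[ia]; b_scf <- blocks$scaffold[ib]
        if (a_scf == b_scf) stop("misjoin junctions must lie in different scaffolds")
        split_at <- function(blocks, i, pos, tag) {
          b <- blocks[i]
          splice_blocks(blocks, i, rbind(
            data.table(scaffold = b$scaffold, src_start = b$src_start, src_end = pos,
                       strand = "+", tag = NA_character_),
            data.table(scaffold = b$scaffold, src_start = pos, src_end = pos,
                       strand = "+", tag = tag),   # junction marker
            data.table(scaffold = b$scaffold, src_start = pos, src_end = b$src_end,
                       strand = "+", tag = NA_character_)))
        }
        tag_a <- sprintf("misjoin_%d_a", k); tag_b <- sprintf("misjoin_%d_b", k)
        blocks <- split_at(blocks, ia, s, tag_a)
        blocks <- split_at(blocks, find_block(blocks, s2, s2), s2, tag_b)
        ## swap everything at/after each junction marker between the scaffolds
        pos_a <- which(blocks$tag == tag_a)
        pos_b <- which(blocks$tag == tag_b)
        rows_a <- which(blocks$scaffold == a_scf & seq_len(nrow(blocks)) >= pos_a)
        rows_b <- which(blocks$scaffold == b_scf & seq_len(nrow(blocks)) >= pos_b)
        tail_a <- blocks[rows_a]; tail_b <- blocks[rows_b]
        tail_a[, scaffold := b_scf]; tail_b[, scaffold := a_scf]
        head_a <- blocks[blocks$scaffold == a_scf & seq_len(nrow(blocks)) < pos_a]
        head_b <- blocks[blocks$scaffold == b_scf & seq_len(nrow(blocks)) < pos_b]
        others <- blocks[!blocks$scaffold %in% c(a_scf, b_scf)]
        blocks <- rbind(others, head_a, tail_b, head_b, tail_a)
        setorder(blocks, scaffold)
        truth_meta[[k]] <- data.table(kind = "misjoin", tag = c(tag_a, tag_b),
                                      size = NA_real_)
      } else stop("unknown error kind: ", kind)
    }
  }
  ## assembly coordinates from cumulated block widths
  blocks[, width := src_end - src_start]
  blocks[, asm_start := cumsum(c(0, width[-.N])), by = scaffold]
  blocks[, asm_end := asm_start + width]
  lengths <- blocks[, .(len = sum(width)), by = scaffold]
  lengths <- setNames(lengths$len, lengths$scaffold)[ids]
  ## resolve truth intervals on the final assembly
  truth <- data.table(kind = character(), scaffold = character(), start = numeric(),
                      end = numeric(), size = numeric())
  if (length(truth_meta)) {
    tm <- rbindlist(truth_meta)
    hit <- blocks[!is.na(tag)][tm, on = "tag"]
    truth <- hit[, .(kind, scaffold, start = asm_start, end = asm_end, size)]
    setorder(truth, scaffold, start)
  }
  ## sequences: substrings of the genome, '-' blocks reverse-complemented
  seq_blocks <- blocks[width > 0]
  pieces <- substring(genome$seq, seq_blocks$src_start + 1, seq_blocks$src_end)
  neg <- seq_blocks$strand == "-"
  if (any(neg)) pieces[neg] <- revcomp(pieces[neg])
  records <- vapply(split(pieces, factor(seq_blocks$scaffold, levels = ids)),
                    paste, character(1), collapse = "")
  structure(list(records = records, lengths = lengths, blocks = blocks[],
                 truth = truth[], adjacency = adjacency),
            class = "ml_assembly")
}

#' @export
print.ml_assembly <- function(x, ...) {
  cat(sprintf("<ml_assembly> %d scaffolds, %.1f Mb, %d injected errors, %d true adjacencies\n",
              length(x$records), sum(x$lengths) / 1e6, nrow(x$truth), nrow(x$adjacency)))
  invisible(x)
}

#' Simulate mate-pair placements on an assembly
#'
#' Draws pairs on the TRUE genome -- insert from a Normal(`lib$mu`,
#' `lib$sigma`) truncated below at `2*read_len` (overlapping-read pairs are
#' discarded by construction), left outer coordinate uniform -- and
#' projects each read through the assembly's block map. Reads falling in
#' deleted sequence are unmapped (their mates become orphans); reads in
#' duplicated sequence map to both copies (`n_hits = 2`); reads inside
#' inverted sequence flip strand. With `multimap_aware`, reads fully inside
#' a repeat copy additionally get `n_hits` equal to the family copy
#' number. `dup_rate` of the pairs are emitted twice (PCR-style
#' duplicates).
#'
#' The reads are emitted as idealized placements, so the assessment and
#' scaffolding machinery is exercised closed-loop without an external
#' aligner.
#'
#' @param genome An `ml_genome`.
#' @param assembly An `ml_assembly` derived from it ([inject_errors()]).
#' @param lib A [library_model()].
#' @param read_len Read length in bp (100--250; default 250).
#' @param coverage Sequence coverage of the reads (default 0.75).
#' @param geometry Library read geometry (default `"outward"`).
#' @param dup_rate Fraction of pairs duplicated (default 0).
#' @param multimap_aware Give repeat-derived reads their family copy number
#'   as `n_hits` (default `TRUE`).
#' @param seed Random seed; `NULL` uses the current RNG state.
#' @return A list: `placements` (placement table on the assembly) and
#'   `truth` (data.table: `pair_id`, `g_start`, `insert` on the genome).
#' @export
simulate_matepairs <- function(genome, assembly, lib = library_model(),
                               read_len = 250L, coverage = 0.75,
                               geometry = c("outward", "inward"),
                               dup_rate = 0, multimap_aware = TRUE, seed = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(inherits(genome, "ml_genome"), inherits(assembly, "ml_assembly"))
  if (read_len < 50 || read_len > 250) stop("read_len must be in [50, 250]")
  if (2 * read_len >= genome$length) stop("reads longer than the genome")
  if (lib$mu >= genome$length) stop("insert longer than the genome")
  if (!is.null(seed)) set.seed(seed)
  n_pairs <- round(coverage * genome$length / (2 * read_len))
  ins <- rnorm(n_pairs, lib$mu, lib$sigma)
  for (it in 1:100) {
    bad <- which(ins < 2 * read_len | ins > genome$length - 1)
    if (!length(bad)) break
    ins[bad] <- rnorm(length(bad), lib$mu, lib$sigma)
  }
  ins <- round(ins)
  s <- floor(runif(n_pairs, 0, genome$length - ins))
  pid <- sprintf("p%07d", seq_len(n_pairs))
  left_strand <- if (geometry == "outward") "-" else "+"
  right_strand <- if (geometry == "outward") "+" else "-"
  reads <- rbind(
    data.table(pair_id = pid, mate = 1L, gs = s, ge = s + read_len, gstrand = left_strand),
    data.table(pair_id = pid, mate = 2L, gs = s + ins - read_len, ge = s + ins,
               gstrand = right_strand)
  )
  reads[, rid := .I]
  ## project through the block map (containment join)
  bl <- assembly$blocks[width > 0,
                        .(scaffold, src_start, src_end, asm_start, strand,
                          bs = src_start, be = src_end - 1)]
  setkey(bl, bs, be)
  reads[, `:=`(qs = gs, qe = ge - 1)]
  hits <- foverlaps(reads, bl, by.x = c("qs", "qe"), type = "within", nomatch = NULL)
  setorder(hits, rid, scaffold, asm_start)
  hits[, n_blk := .N, by = rid]
  hits <- hits[!duplicated(rid)]
  hits[, a_start := fifelse(strand == "+", asm_start + (gs - src_start),
                            asm_start + (src_end - ge))]
  hits[, a_strand := fifelse(strand == "+", gstrand,
                             fifelse(gstrand == "+", "-", "+"))]
  hits[, n_hits := n_blk]
  if (multimap_aware && nrow(genome$repeats)) {
    rp <- genome$repeats[, .(copies, rs = start, re = end - 1)]
    setkey(rp, rs, re)
    inrep <- foverlaps(reads[, .(rid, qs, qe)], rp, by.x = c("qs", "qe"),
                       type = "within", nomatch = NULL)
    inrep <- inrep[, .(rep_hits = max(copies)), by = rid]
    hits[inrep, n_hits := pmax(n_hits, i.rep_hits), on = "rid"]
  }
  pl <- placement_table(hits$pair_id, hits$mate, hits$scaffold, hits$a_start,
                        hits$a_start + read_len,
                        hits$a_strand, hits$n_hits,
                        read_id = paste0(hits$pair_id, "/", hits$mate))
  if (dup_rate > 0) {
    n_dup <- round(dup_rate * n_pairs)
    if (n_dup > 0) {
      dup_ids <- sample(pid, n_dup)
      dup <- pl[pair_id %in% dup_ids]
      dup[, pair_id := paste0(pair_id, "d")]
      dup[, read_id := paste0(pair_id, "/", mate)]
      pl <- rbind(pl, dup)
    }
  }
  list(placements = pl[order(pair_id, mate)],
       truth = data.table(pair_id = pid, g_start = s, insert = ins))
}

#' Standard error-injection layout for a fixture genome
#'
#' Deterministically lays out deletions, insertions, inversions and
#' chimeric junctions on a genome cut into equal scaffolds: intra-scaffold
#' error slots sit at fixed offsets (12%--68% of the scaffold, >50 kb
#' apart and >100 kb from scaffold ends), error kinds are shuffled across
#' slots with the seed, and tail-swap junctions sit at 85% of the paired
#' scaffolds.
#'
#' @param genome An `ml_genome`.
#' @param n_scaffolds Number of equal scaffolds (default 10).
#' @param n_del,n_ins,n_inv Counts of each intra-scaffold error kind.
#' @param n_junctions Number of chimeric junctions (even; two per tail
#'   swap), default 10.
#' @param del_size,ins_size,inv_size Error sizes in bp.
#' @param seed Seed used to shuffle kinds over slots.
#' @return A list: `fragments` (cut positions) and `errors` (spec table
#'   for [inject_errors()]).
#' @export
fixture_error_spec <- function(genome, n_scaffolds = 10L, n_del = 20L, n_ins = 20L,
                               n_inv = 10L, n_junctions = 10L, del_size = 15000,
                               ins_size = 15000, inv_size = 50000, seed = 1L) {
  sl <- genome$length / n_scaffolds
  n_intra <- n_del + n_ins + n_inv
  per_scf <- ceiling(n_intra / n_scaffolds)
  offsets <- seq(0.12 * sl, 0.68 * sl, length.out = per_scf)
  slots <- as.vector(outer(offsets, (seq_len(n_scaffolds) - 1) * sl, `+`))
  set.seed(seed)
  kinds <- sample(c(rep("deletion", n_del), rep("insertion", n_ins),
                    rep("inversion", n_inv),
                    rep(NA_character_, length(slots) - n_intra)))
  sizes <- c(deletion = del_size, insertion = ins_size, inversion = inv_size)
  keep <- !is.na(kinds)
  errors <- data.table(kind = kinds[keep], start = slots[keep],
                       size = sizes[kinds[keep]], start2 = NA_real_)
  if (n_junctions > 0L) {
    if (n_junctions %% 2L != 0L) stop("n_junctions must be even (two per tail swap)")
    n_swaps <- n_junctions / 2L
    if (2L * n_swaps > n_scaffolds) stop("not enough scaffolds for the tail swaps")
    a <- seq(1L, by = 2L, length.out = n_swaps)
    errors <- rbind(errors, data.table(
      kind = "misjoin",
      start = (a - 1) * sl + 0.85 * sl,
      size = NA_real_,
      start2 = a * sl + 0.85 * sl
    ))
  }
  list(fragments = sl * seq_len(n_scaffolds - 1L), errors = errors[])
}

#' Fragmentation layout for the scaffolding fixture
#'
#' Cuts a genome into `n_contigs` pieces of jittered size (each at least
#' 60% of the mean), so every contig comfortably exceeds the library's
#' upper span and true adjacencies are recoverable.
#'
#' @param genome_length Genome length in bp.
#' @param n_contigs Number of contigs (default 100).
#' @param seed Seed for the jitter.
#' @return Numeric vector of cut positions for [inject_errors()].
#' @export
fixture_fragments <- function(genome_length, n_contigs = 100L, seed = 1L) {
  set.seed(seed)
  size <- genome_length / n_contigs
  base <- size * seq_len(n_contigs - 1L)
  jit <- runif(n_contigs - 1L, -0.2 * size, 0.2 * size)
  round(base + jit)
}

#' Score discrepancy calls against injected-error truth
#'
#' A truth record counts as detected when a discrepancy of the matching
#' class overlaps its assembly interval extended by `lib$upper` on both
#' sides (a mate-pair method localizes an error to within roughly one
#' insert length). Class map: deletion -> DELETION, insertion ->
#' INSERTION, inversion -> MISORIENTATION, misjoin -> BREAK or NEWJOIN (a
#' chimeric junction shows up as a break when its true counterpart is
#' absent and as a cross-scaffold join when it is present elsewhere in the
#' assembly).
#'
#' @param discrepancies A merged discrepancy table.
#' @param truth The `truth` table of an `ml_assembly`.
#' @param lib A [library_model()].
#' @return A list: `per_truth` (truth with a `detected` flag) and `rates`
#'   (data.table of `kind`, `n`, `n_detected`, `rate`).
#' @export
error_recovery <- function(discrepancies, truth, lib = library_model()) {
  d <- as.data.table(discrepancies)
  t <- copy(as.data.table(truth))
  class_map <- list(deletion = "DELETION", insertion = "INSERTION",
                    inversion = "MISORIENTATION", misjoin = c("BREAK", "NEWJOIN"))
  tol <- lib$upper
  t[, detected := vapply(seq_len(.N), function(i) {
    ks <- class_map[[kind[i]]]
    nrow(d[scaffold == t$scaffold[i] & kind %in% ks &
             start < t$end[i] + tol & end > t$start[i] - tol]) > 0L
  }, logical(1))]
  rates <- t[, .(n = .N, n_detected = sum(detected), rate = mean(detected)), by = kind]
  list(per_truth = t[], rates = rates[])
}

#' Count discrepancy calls not explained by injected errors
#'
#' The complement of [error_recovery()]: INSERTION, DELETION,
#' MISORIENTATION and BREAK calls that overlap no truth interval (extended
#' by `lib$upper`) of any kind.
#'
#' @inheritParams error_recovery
#' @return Integer count of unexplained calls.
#' @export
false_positive_calls <- function(discrepancies, truth, lib = library_model()) {
  d <- as.data.table(discrepancies)
  d <- d[kind %in% c("INSERTION", "DELETION", "MISORIENTATION", "BREAK")]
  if (!nrow(d)) return(0L)
  t <- as.data.table(truth)
  tol <- lib$upper
  explained <- vapply(seq_len(nrow(d)), function(i) {
    nrow(t[scaffold == d$scaffold[i] &
             start < d$end[i] + tol & end > d$start[i] - tol]) > 0L
  }, logical(1))
  sum(!explained)
}

#' Score scaffold paths against true adjacencies
#'
#' A true adjacency (a before b, both forward) is recovered when a path
#' holds the two contigs consecutively in a compatible direction (`a+ b+`
#' or `b- a-`). Every other realized join -- wrong neighbour or wrong
#' relative strand -- is counted as wrong.
#'
#' @param paths A scaffold-path table ([linearize()]).
#' @param adjacency The `adjacency` table of an `ml_assembly`.
#' @return A list: `recall`, `n_true`, `n_recovered`, `n_joins`, `n_wrong`,
#'   `joins` (the realized joins with a `correct` flag).
#' @export
adjacency_eval <- function(paths, adjacency) {
  p <- as.data.table(paths)
  joins <- p[, if (.N > 1L) .(a = contig[-.N], ao = orient[-.N],
                              b = contig[-1L], bo = orient[-1L]), by = object]
  adj <- as.data.table(adjacency)
  if (!nrow(joins)) {
    return(list(recall = 0, n_true = nrow(adj), n_recovered = 0L, n_joins = 0L,
                n_wrong = 0L, joins = joins))
  }
  key_fwd <- paste(adj$a_id, adj$b_id)
  joins[, correct := (ao == bo) &
          fifelse(ao == "+", paste(a, b) %in% key_fwd, paste(b, a) %in% key_fwd)]
  recovered <- unique(joins[correct == TRUE,
                            fifelse(ao == "+", paste(a, b), paste(b, a))])
  list(recall = length(recovered) / max(1L, nrow(adj)), n_true = nrow(adj),
       n_recovered = length(recovered), n_joins = nrow(joins),
       n_wrong = sum(!joins$correct), joins = joins[])
}

#' Coverage sweep of adjacency recovery and error detection
#'
#' Re-runs the closed-loop benchmark over a grid of sequence coverages
#' (and optionally read lengths): per replicate, one fragmented genome for
#' adjacency recovery and one error-bearing assembly for detection, each
#' simulated and analysed at every grid point with the default cleaning
#' and assessment parameters.
#'
#' @param coverages Numeric vector of sequence coverages.
#' @param read_lens Integer vector of read lengths (default 250).
#' @param n_reps Replicates per grid cell (default 2).
#' @param seed Base seed; replicate r uses `seed + r` for the fixtures.
#' @param genome_length Fixture genome size (default 3 Mb -- large enough
#'   for tens of independent errors yet quick to scan).
#' @param n_contigs Contigs in the fragmentation fixture (default 30).
#' @return A `data.table`: one row per (read_len, coverage, rep) with
#'   `adjacency_recovery`, `error_detection`, `false_positives`.
#' @export
sweep_coverage <- function(coverages = c(0.1, 0.25, 0.5, 0.75, 1.0),
                           read_lens = 250L, n_reps = 2L, seed = 1L,
                           genome_length = 3e6, n_contigs = 30L) {
  lib <- library_model()
  out <- list()
  for (r in seq_len(n_reps)) {
    g <- sim_genome(genome_length, n_families = 2L, copies = 10L, seed = seed + r)
    frag <- inject_errors(g, fragments = fixture_fragments(genome_length, n_contigs,
                                                           seed = seed + r))
    spec <- fixture_error_spec(g, n_scaffolds = 3L, n_del = 3L, n_ins = 3L,
                               n_inv = 2L, n_junctions = 2L, seed = seed + r)
    errasm <- inject_errors(g, errors = spec$errors, fragments = spec$fragments)
    for (rl in read_lens) for (cv in coverages) {
      sub_seed <- seed + 1000L * r + round(10000 * cv) + rl
      det <- NA_real_; fp <- NA_integer_; adj <- NA_real_
      if (cv > 0) {
        sim_a <- simulate_matepairs(g, errasm, lib, read_len = rl, coverage = cv,
                                    seed = sub_seed)
        cl_a <- clean_placements(sim_a$placements, profile = "assessment",
                                 lengths = errasm$lengths)
        asmnt <- assess_assembly(cl_a$pairs, errasm$lengths, lib)
        rec <- error_recovery(asmnt$discrepancies, errasm$truth, lib)
        det <- mean(rec$per_truth$detected)
        fp <- false_positive_calls(asmnt$discrepancies, errasm$truth, lib)
        sim_s <- simulate_matepairs(g, frag, lib, read_len = rl, coverage = cv,
                                    seed = sub_seed + 1L)
        cl_s <- clean_placements(sim_s$placements, profile = "scaffolding",
                                 lengths = frag$lengths)
        sc <- scaffold_assembly(cl_s$pairs, frag$records, lib)
        adj <- adjacency_eval(sc$paths, frag$adjacency)$recall
      } else { det <- 0; fp <- 0L; adj <- 0 }
      out <- c(out, list(data.table(read_len = rl, coverage = cv, rep = r,
                                    adjacency_recovery = adj, error_detection = det,
                                    false_positives = fp)))
    }
  }
  rbindlist(out)
}
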