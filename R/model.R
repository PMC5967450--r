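## Domain types and coordinate/orientation conventions shared by all modules.
##
## Placements and pairs are plain data.tables so that every downstream filter
## is a vectorised table operation:
##   placements: read_id, pair_id, mate (1L/2L), scaffold, start, end,
##               strand ("+"/"-"), n_hits
##   pairs:      pair_id, scaffold1, start1, end1, strand1, n_hits1,
##               scaffold2, start2, end2, strand2, n_hits2,
##               same_scaffold, span, orientation
## Coordinates are 0-based half-open; span is the OUTER distance (the insert
## size proxy): max(end1, end2) - min(start1, start2) on one scaffold.

#' Library insert-size model
#'
#' Describes a jumping library by the mean and standard deviation of its
#' insert (outer-distance) distribution, and derives the consistency band
#' used to classify mate-pair spans: spans inside `[lower, upper]` =
#' `mu +/- 3*sigma` are consistent; larger spans indicate an aberrant
#' insertion in the assembly, smaller spans an aberrant deletion.
#'
#' The defaults describe a fosmid-scale jumping library with a 37,725-bp
#' mean insert. With `sigma = 4200` the band is 25,125--50,325 bp, i.e. the
#' familiar ~25-kb / ~50-kb cutoffs for a ~38-kb library. `sigma` is a real
#' parameter of the library, not a constant: estimate it from data with
#' [estimate_insert_distribution()] whenever alignments are available.
#'
#' @param mu Mean insert size in bp (> 0).
#' @param sigma Standard deviation of the insert size in bp (> 0).
#' @return An object of class `library_model` with fields `mu`, `sigma`,
#'   `lower = mu - 3*sigma`, `upper = mu + 3*sigma`.
#' @examples
#' lib <- library_model(37725, 4200)
#' lib$lower  # 25125
#' lib$upper  # 50325
#' @export
library_model <- function(mu = 37725, sigma = 4200) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("'mu' must be a single positive number")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive number")
  structure(
    list(mu = as.numeric(mu), sigma = as.numeric(sigma),
         lower = as.numeric(mu - 3 * sigma), upper = as.numeric(mu + 3 * sigma)),
    class = "library_model"
  )
}

#' @export
print.library_model <- function(x, ...) {
  cat(sprintf("<library_model> insert mu = %.0f bp, sigma = %.0f bp\n", x$mu, x$sigma))
  cat(sprintf("  consistency band (mu +/- 3 sigma): [%.0f, %.0f] bp\n", x$lower, x$upper))
  invisible(x)
}

#' Assessment window parameters
#'
#' Parameters of the driver/follower window scan: a discrepancy call needs
#' at least `min_support` unique neighbouring reads whose starts fit in a
#' "driver" window narrower than `driver_max` and whose mates fit in a
#' "follower" window narrower than `follower_max`. `depth_max` is the
#' repeat filter: read placements overlapping regions of per-base depth
#' greater than `depth_max` are discarded before assessment.
#'
#' @param min_support Minimum reads per window (>= 2), default 5.
#' @param driver_max Maximum driver window width in bp, default 10,000.
#' @param follower_max Maximum follower window width in bp, default 20,000.
#' @param depth_max Maximum tolerated per-base read depth, default 5.
#' @return An object of class `assess_params`.
#' @export
assess_params <- function(min_support = 5L, driver_max = 10000, follower_max = 20000,
                          depth_max = 5L) {
  min_support <- as.integer(min_support)
  if (is.na(min_support) || min_support < 2L) stop("'min_support' must be >= 2")
  if (!(driver_max > 0) || !(follower_max > 0)) stop("window widths must be positive")
  if (driver_max >= follower_max) stop("'driver_max' must be smaller than 'follower_max'")
  if (as.integer(depth_max) < 1L) stop("'depth_max' must be >= 1")
  structure(list(min_support = min_support, driver_max = as.numeric(driver_max),
                 follower_max = as.numeric(follower_max), depth_max = as.integer(depth_max)),
            class = "assess_params")
}

#' @export
print.assess_params <- function(x, ...) {
  cat(sprintf("<assess_params> support >= %d, driver < %.0f bp, follower < %.0f bp, depth <= %d\n",
              x$min_support, x$driver_max, x$follower_max, x$depth_max))
  invisible(x)
}

#' Construct a read-placement table
#'
#' Builds the canonical placement table used throughout the package. One row
#' per mapped read: which scaffold, where (0-based half-open), on which
#' strand, and in how many equally good locations (`n_hits`).
#'
#' @param pair_id Character vector of pair identifiers.
#' @param mate Integer vector in \{1, 2\}: which end of the pair.
#' @param scaffold Character vector of scaffold identifiers.
#' @param start,end Numeric vectors, 0-based half-open coordinates.
#' @param strand Character vector of "+" or "-".
#' @param n_hits Integer vector, number of equally good mapping locations
#'   (>= 1). Default 1 (unique).
#' @param read_id Optional read identifiers; default `paste0(pair_id, "/", mate)`.
#' @return A `data.table` with columns `read_id`, `pair_id`, `mate`,
#'   `scaffold`, `start`, `end`, `strand`, `n_hits`.
#' @export
placement_table <- function(pair_id, mate, scaffold, start, end, strand,
                            n_hits = 1L, read_id = NULL) {
  n <- length(pair_id)
  if (is.null(read_id)) read_id <- paste0(pair_id, "/", mate)
  dt <- data.table(
    read_id = as.character(read_id), pair_id = as.character(pair_id),
    mate = as.integer(mate), scaffold = as.character(scaffold),
    start = as.numeric(start), end = as.numeric(end),
    strand = as.character(strand), n_hits = as.integer(rep_len(n_hits, n))
  )
  validate_placements(dt)
  dt[]
}

#' Validate a placement table
#'
#' Checks coordinate sanity (`0 <= start < end`), strand values, `n_hits >= 1`
#' and, when scaffold lengths are supplied, that no placement extends past the
#' end of its scaffold.
#'
#' @param placements A placement table (see [placement_table()]).
#' @param lengths Optional named numeric vector of scaffold lengths.
#' @return The table, invisibly; stops on violation.
#' @export
validate_placements <- function(placements, lengths = NULL) {
  req <- c("read_id", "pair_id", "mate", "scaffold", "start", "end", "strand", "n_hits")
  miss <- setdiff(req, names(placements))
  if (length(miss)) stop("placement table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(placements)) {
    if (any(placements$start < 0) || any(placements$end <= placements$start))
      stop("placements must satisfy 0 <= start < end")
    if (!all(placements$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (any(placements$n_hits < 1L)) stop("n_hits must be >= 1")
    if (!all(placements$mate %in% c(1L, 2L))) stop("mate must be 1 or 2")
    if (!is.null(lengths)) {
      len <- lengths[placements$scaffold]
      if (anyNA(len)) stop("placement on unknown scaffold: ",
                           placements$scaffold[which(is.na(len))[1]])
      if (any(placements$end > len))
        stop("placement extends beyond scaffold end")
    }
  }
  invisible(placements)
}

## Orientation of a same-scaffold pair against the configured library
## geometry. Leftmost read = smaller start. "outward" geometry (RF, the
## circularisation chemistry of fosmid jumping libraries) expects the
## leftmost read on '-' and the rightmost on '+'; "inward" (FR) the reverse.
## Same-strand pairs are "reversed" (the inversion signal); opposite strands
## arranged against the geometry are "tandem".
orient_class <- function(left_strand, right_strand, geometry = "outward") {
  exp_left <- if (geometry == "outward") "-" else "+"
  data.table::fifelse(left_strand == right_strand, "reversed",
                      data.table::fifelse(left_strand == exp_left, "expected", "tandem"))
}

#' Pair up read placements
#'
#' Joins the two mates of each pair into one row, computes the outer-distance
#' span for same-scaffold pairs and classifies the pair orientation against
#' the library geometry. Placements whose mate is missing are returned
#' separately as orphans.
#'
#' The two placements of a pair are stored in canonical order (by scaffold
#' id, then start), so pairing is symmetric in the two mates.
#'
#' @param placements A placement table ([placement_table()]); at most one
#'   placement per (pair_id, mate).
#' @param geometry `"outward"` (default; fosmid jump libraries read outward
#'   after circularisation) or `"inward"`.
#' @return A list with elements `pairs` (one row per complete pair) and
#'   `orphans` (placements lacking a mapped mate).
#' @export
make_pairs <- function(placements, geometry = c("outward", "inward")) {
  geometry <- match.arg(geometry)
  validate_placements(placements)
  if (anyDuplicated(placements[, .(pair_id, mate)]))
    stop("more than one placement per (pair_id, mate); resolve multi-mappers first")
  p1 <- placements[mate == 1L]
  p2 <- placements[mate == 2L]
  common <- intersect(p1$pair_id, p2$pair_id)
  orphans <- placements[!pair_id %in% common]
  a <- p1[pair_id %in% common][order(pair_id)]
  b <- p2[pair_id %in% common][order(pair_id)]
  ## canonical order: by (scaffold, start)
  swap <- (b$scaffold < a$scaffold) | (b$scaffold == a$scaffold & b$start < a$start)
  sw <- function(x, y) { x[swap] <- y[swap]; x }
  pairs <- data.table(
    pair_id = a$pair_id,
    scaffold1 = sw(a$scaffold, b$scaffold), start1 = sw(a$start, b$start),
    end1 = sw(a$end, b$end), strand1 = sw(a$strand, b$strand),
    n_hits1 = sw(a$n_hits, b$n_hits),
    scaffold2 = sw(b$scaffold, a$scaffold), start2 = sw(b$start, a$start),
    end2 = sw(b$end, a$end), strand2 = sw(b$strand, a$strand),
    n_hits2 = sw(b$n_hits, a$n_hits)
  )
  pairs[, same_scaffold := scaffold1 == scaffold2]
  pairs[, span := fifelse(same_scaffold, pmax(end1, end2) - pmin(start1, start2), NA_real_)]
  pairs[, orientation := fifelse(same_scaffold,
                                 orient_class(strand1, strand2, geometry),
                                 NA_character_)]
  list(pairs = pairs[order(pair_id)][], orphans = orphans[])
}

#' Build a single aligned pair from two placements
#'
#' Convenience wrapper around [make_pairs()] for exactly one pair: computes
#' the outer-distance span and the orientation class of the two placements.
#'
#' @param p1,p2 Single-row placement tables with the same `pair_id` and
#'   mate indices 1 and 2.
#' @inheritParams make_pairs
#' @return A one-row pair table (see [make_pairs()]).
#' @export
pair_from_placements <- function(p1, p2, geometry = c("outward", "inward")) {
  geometry <- match.arg(geometry)
  if (nrow(p1) != 1L || nrow(p2) != 1L) stop("p1 and p2 must be single placements")
  if (p1$pair_id != p2$pair_id) stop("placements belong to different pairs")
  res <- make_pairs(rbind(p1, p2), geometry = geometry)
  if (nrow(res$pairs) != 1L) stop("placements do not form a complete pair")
  res$pairs
}

#' Convert a pair table back to placements
#'
#' The inverse of [make_pairs()]: one placement row per read.
#'
#' @param pairs A pair table.
#' @return A placement table.
#' @export
pairs_to_placements <- function(pairs) {
  if (!nrow(pairs)) return(placement_table(character(), integer(), character(),
                                           numeric(), numeric(), character()))
  rbind(
    pairs[, .(read_id = paste0(pair_id, "/1"), pair_id, mate = 1L,
              scaffold = scaffold1, start = start1, end = end1,
              strand = strand1, n_hits = n_hits1)],
    pairs[, .(read_id = paste0(pair_id, "/2"), pair_id, mate = 2L,
              scaffold = scaffold2, start = start2, end = end2,
              strand = strand2, n_hits = n_hits2)]
  )
}
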