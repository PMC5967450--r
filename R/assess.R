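## The assessment engine. Every mapped pair contributes two "rows": each
## read in turn acts as a potential driver with its mate as the follower.
## A window is a MAXIMAL set of rows, all on one scaffold with all mates on
## one scaffold, whose read starts fit in an interval < driver_max and
## whose mate starts fit in an interval < follower_max, supported by at
## least min_support distinct pairs. Windows are then classified in a fixed
## decision order: follower on another scaffold -> NEWJOIN; follower absent
## -> BREAK; reversed orientation consensus -> MISORIENTATION; median span
## above/below the library band -> INSERTION/DELETION; else CONSISTENT.

## one pair -> two driver rows (read vs mate swapped)
pairs_to_rows <- function(pairs) {
  if (!nrow(pairs))
    return(data.table(row_id = integer(), pair_id = character(), scaffold = character(),
                      start = numeric(), end = numeric(), mate_scaffold = character(),
                      mate_start = numeric(), mate_end = numeric(), span = numeric(),
                      orientation = character()))
  rows <- rbind(
    pairs[, .(pair_id, scaffold = scaffold1, start = start1, end = end1,
              mate_scaffold = scaffold2, mate_start = start2, mate_end = end2,
              span, orientation)],
    pairs[, .(pair_id, scaffold = scaffold2, start = start2, end = end2,
              mate_scaffold = scaffold1, mate_start = start1, mate_end = end1,
              span, orientation)]
  )
  setorder(rows, scaffold, start, mate_scaffold, mate_start, pair_id)
  rows[, row_id := .I]
  rows[]
}

## maximal qualifying windows within one (scaffold, mate_scaffold) group.
## starts/mates are integer-valued; rows assumed sorted by start.
## Returns a list of integer vectors of local row indices.
scan_group <- function(starts, mates, pair_ids, min_support, driver_max, follower_max) {
  n <- length(starts)
  if (n < min_support) return(list())
  jmax <- findInterval(starts + driver_max - 1, starts)
  out <- vector("list", 64L); n_out <- 0L
  prev_j <- -1L
  for (i in seq_len(n)) {
    j <- jmax[i]
    ## anchor is useful only when the driver run gains a new rightmost read
    if (j == prev_j) next
    prev_j <- j
    if (j - i + 1L < min_support) next
    idx <- i:j
    om <- order(mates[idx])
    ms <- mates[idx][om]
    ecnt <- findInterval(ms + follower_max - 1, ms)
    prev_e <- -1L
    for (k in seq_along(ms)) {
      e <- ecnt[k]
      if (e == prev_e) next      # strict subset of the previous follower run
      prev_e <- e
      if (e - k + 1L < min_support) next
      memb <- idx[om[k:e]]
      if (length(unique(pair_ids[memb])) < min_support) next
      n_out <- n_out + 1L
      if (n_out > length(out)) out <- c(out, vector("list", length(out)))
      out[[n_out]] <- sort(memb)
    }
  }
  if (!n_out) return(list())
  out <- out[seq_len(n_out)]
  ## dedupe (the same maximal set is reached from several anchors)
  out <- out[!duplicated(vapply(out, paste, character(1), collapse = ","))]
  ## drop non-maximal sets: S is contained in S' iff S's bounding box fits
  ## inside S''s generating rectangle [min start, +driver_max) x
  ## [min mate, +follower_max), because S' holds ALL rows of that rectangle
  m <- length(out)
  if (m > 1L) {
    lo_s <- vapply(out, function(ix) starts[ix[1]], numeric(1))
    hi_s <- vapply(out, function(ix) starts[ix[length(ix)]], numeric(1))
    lo_m <- vapply(out, function(ix) min(mates[ix]), numeric(1))
    hi_m <- vapply(out, function(ix) max(mates[ix]), numeric(1))
    sz <- lengths(out)
    o <- order(lo_s)
    los <- lo_s[o]; his <- hi_s[o]; lom <- lo_m[o]; him <- hi_m[o]; szs <- sz[o]
    keep <- rep(TRUE, m)
    for (a in seq_len(m)) {
      ## only a larger set whose driver rectangle starts within driver_max
      ## to the left can contain this one
      fb <- findInterval(los[a] - driver_max, los) + 1L
      ub <- a
      while (ub < m && los[ub + 1L] <= los[a]) ub <- ub + 1L
      b <- fb:ub
      b <- b[b != a]
      if (length(b) &&
          any(szs[b] > szs[a] & his[a] < los[b] + driver_max &
              lom[a] >= lom[b] & him[a] < lom[b] + follower_max))
        keep[a] <- FALSE
    }
    out <- out[o][keep]
  }
  out
}

## maximal runs of >= min_support co-located leftover reads (width < driver_max)
leftover_runs <- function(starts, pair_ids, min_support, driver_max) {
  n <- length(starts)
  if (n < min_support) return(list())
  jmax <- findInterval(starts + driver_max - 1, starts)
  out <- list(); prev_j <- -1L
  for (i in seq_len(n)) {
    j <- jmax[i]
    if (j == prev_j) next
    prev_j <- j
    if (j - i + 1L < min_support) next
    if (length(unique(pair_ids[i:j])) < min_support) next
    out <- c(out, list(i:j))
  }
  out
}

#' Scan mate pairs for driver/follower window evidence
#'
#' Finds every maximal set of at least `min_support` unique neighbouring
#' reads whose starts fit in a driver window narrower than `driver_max` and
#' whose mates, on a single scaffold, fit in a follower window narrower
#' than `follower_max`. Reads that support no such window but co-locate
#' (>= `min_support` within a driver window) yield follower-absent
#' evidence, the raw material for mis-join (BREAK) calls.
#'
#' @param pairs A cleaned pair table (assessment profile).
#' @param params An [assess_params()] object.
#' @return A `data.table` of window evidence: `scaffold`, `driver_start`,
#'   `driver_end`, `follower_scaffold` (`NA` = follower absent),
#'   `follower_start`, `follower_end`, `support` (distinct pairs),
#'   `median_span` (same-scaffold windows), `orientation_consensus`
#'   (`expected`/`reversed`/`mixed`), and a `members` list column of
#'   supporting pair ids.
#' @export
scan_windows <- function(pairs, params = assess_params()) {
  rows <- pairs_to_rows(pairs)
  empty <- data.table(scaffold = character(), driver_start = numeric(),
                      driver_end = numeric(), follower_scaffold = character(),
                      follower_start = numeric(), follower_end = numeric(),
                      support = integer(), median_span = numeric(),
                      orientation_consensus = character(), members = list())
  if (!nrow(rows)) return(empty)
  grp <- rows[, .(idx = list(row_id)), by = .(scaffold, mate_scaffold)]
  all_sets <- vector("list", nrow(grp))
  for (g in seq_len(nrow(grp))) {
    ix <- grp$idx[[g]]
    sets <- scan_group(rows$start[ix], rows$mate_start[ix], rows$pair_id[ix],
                       params$min_support, params$driver_max, params$follower_max)
    if (length(sets)) all_sets[[g]] <- lapply(sets, function(s) ix[s])
  }
  all_sets <- unlist(all_sets, recursive = FALSE)
  used <- logical(nrow(rows))
  if (length(all_sets)) used[unlist(all_sets)] <- TRUE
  ## follower-absent evidence from reads supporting no window
  absent_sets <- list()
  left <- rows[!used[row_id]]
  if (nrow(left)) {
    for (sc in unique(left$scaffold)) {
      l <- left[scaffold == sc]
      runs <- leftover_runs(l$start, l$pair_id, params$min_support, params$driver_max)
      absent_sets <- c(absent_sets, lapply(runs, function(r) l$row_id[r]))
    }
  }
  n_f <- length(all_sets); n_a <- length(absent_sets)
  if (n_f + n_a == 0L) return(empty)
  sets <- c(all_sets, absent_sets)
  mm <- rows[unlist(sets)]
  mm[, win := rep(seq_along(sets), lengths(sets))]
  mm[, absent := win > n_f]
  ext <- mm[, .(scaffold = scaffold[1], driver_start = min(start), driver_end = max(end),
                follower_scaffold = mate_scaffold[1],
                follower_start = min(mate_start), follower_end = max(mate_end),
                absent = absent[1]),
            by = win]
  mmu <- unique(mm, by = c("win", "pair_id"))
  mmu[, is_rev := orientation == "reversed"]
  mmu[, is_exp := orientation == "expected"]
  stats <- mmu[, .(support = .N, median_span = median(span),
                   frac_rev = mean(is_rev), frac_exp = mean(is_exp)),
               by = win]
  membs <- mmu[, .(members = list(sort(pair_id))), by = win]
  w <- ext[stats, on = "win"][membs, on = "win"]
  same <- w[, !absent & follower_scaffold == scaffold]
  w[, orientation_consensus := fifelse(
    same & frac_rev > 0.5, "reversed",
    fifelse(same & frac_exp > 0.5, "expected",
            fifelse(same, "mixed", NA_character_)))]
  w[!same, median_span := NA_real_]
  w[absent == TRUE, `:=`(follower_scaffold = NA_character_,
                         follower_start = NA_real_, follower_end = NA_real_)]
  w <- w[, .(scaffold, driver_start, driver_end, follower_scaffold,
             follower_start, follower_end, support, median_span,
             orientation_consensus, members)]
  setorder(w, scaffold, driver_start, driver_end, follower_scaffold, na.last = TRUE)
  w[]
}

#' Classify window evidence into discrepancy calls
#'
#' Fixed decision order per window: (1) follower on a different scaffold ->
#' `NEWJOIN`; (2) follower absent -> `BREAK`; (3) reversed orientation
#' consensus -> `MISORIENTATION`; (4) median span above `lib$upper` ->
#' `INSERTION`; (5) median span below `lib$lower` -> `DELETION`; (6)
#' otherwise `CONSISTENT`. The reported interval is the full driver-to-
#' follower extent for same-scaffold windows and the driver interval for
#' NEWJOIN/BREAK windows.
#'
#' @param windows Window evidence from [scan_windows()].
#' @param lib A [library_model()].
#' @return A discrepancy table: `scaffold`, `start`, `end`, `kind`,
#'   `support`, `median_span`, `follower_scaffold`, `follower_start`,
#'   `follower_end`, `orientation_consensus`.
#' @export
classify_windows <- function(windows, lib) {
  w <- copy(as.data.table(windows))
  if (!nrow(w))
    return(data.table(scaffold = character(), start = numeric(), end = numeric(),
                      kind = character(), support = integer(), median_span = numeric(),
                      follower_scaffold = character(), follower_start = numeric(),
                      follower_end = numeric(), orientation_consensus = character()))
  w[, kind := fcase(
    !is.na(follower_scaffold) & follower_scaffold != scaffold, "NEWJOIN",
    is.na(follower_scaffold), "BREAK",
    orientation_consensus == "reversed", "MISORIENTATION",
    median_span > lib$upper, "INSERTION",
    median_span < lib$lower, "DELETION",
    default = "CONSISTENT"
  )]
  same <- w[, !is.na(follower_scaffold) & follower_scaffold == scaffold]
  w[, start := fifelse(same, pmin(driver_start, follower_start), driver_start)]
  w[, end := fifelse(same, pmax(driver_end, follower_end), driver_end)]
  w[, .(scaffold, start, end, kind, support, median_span, follower_scaffold,
        follower_start, follower_end, orientation_consensus)]
}

#' Filter BREAK calls: scaffold-end exemption and consistency guard
#'
#' Follower-absent evidence indicates a mis-join only when the missing
#' mates cannot be explained benignly. Two guards: (i) drivers within
#' `lib$upper` of a scaffold end are exempt, because their mates
#' legitimately fall off the end of the sequence; (ii) drivers overlapping
#' a CONSISTENT window are exempt, because the locus is independently
#' explained by correctly spanning pairs.
#'
#' @param discrepancies A classified discrepancy table ([classify_windows()]).
#' @param lengths Named numeric vector of scaffold lengths.
#' @param lib A [library_model()].
#' @return The discrepancy table with non-surviving BREAK rows removed.
#' @export
detect_breaks <- function(discrepancies, lengths, lib) {
  d <- as.data.table(discrepancies)
  if (!nrow(d)) return(d)
  br <- d$kind == "BREAK"
  if (!any(br)) return(d)
  len <- lengths[d$scaffold]
  near_end <- d$start < lib$upper | d$end > len - lib$upper
  cons <- d[kind == "CONSISTENT"]
  overlaps_cons <- rep(FALSE, nrow(d))
  if (nrow(cons)) {
    for (i in which(br)) {
      cc <- cons[scaffold == d$scaffold[i] & start < d$end[i] & end > d$start[i]]
      overlaps_cons[i] <- nrow(cc) > 0L
    }
  }
  d[!(br & (near_end | overlaps_cons))]
}

#' Merge overlapping discrepancies of identical class
#'
#' Overlapping or book-ended calls of the same kind on the same scaffold
#' are collapsed into one maximal interval; support is the maximum over the
#' merged calls and the median span their median.
#'
#' @param discrepancies A discrepancy table.
#' @return The merged table, sorted by (scaffold, start).
#' @export
merge_discrepancies <- function(discrepancies) {
  d <- as.data.table(discrepancies)
  if (!nrow(d)) return(d)
  setorder(d, scaffold, kind, start, end)
  d[, grp := {
    g <- integer(.N); run_end <- -Inf; gi <- 0L
    for (i in seq_len(.N)) {
      if (start[i] > run_end) gi <- gi + 1L
      run_end <- max(run_end, end[i])
      g[i] <- gi
    }
    g
  }, by = .(scaffold, kind)]
  out <- d[, .(start = min(start), end = max(end), support = max(support),
               median_span = median(median_span),
               follower_scaffold = if (uniqueN(follower_scaffold) == 1L)
                 follower_scaffold[1] else NA_character_,
               n_windows = .N),
           by = .(scaffold, kind, grp)][, !"grp"]
  setorder(out, scaffold, start, end, kind)
  out[]
}

#' Bin pair coverage along scaffolds
#'
#' Counts, in fixed-width bins, the pairs whose leftmost placement
#' coordinate falls in each bin -- the classic evenness-of-coverage view of
#' a jumping library along an assembly. The final partial bin is included.
#'
#' @param pairs A pair table.
#' @param lengths Named numeric vector of scaffold lengths.
#' @param bin_size Bin width in bp, default 100,000.
#' @return A `data.table`: `scaffold`, `bin_start`, `bin_end`, `n_pairs`.
#' @export
coverage_bins <- function(pairs, lengths, bin_size = 100000) {
  stopifnot(bin_size > 0)
  grid <- rbindlist(lapply(names(lengths), function(sc) {
    starts <- seq(0, max(0, lengths[[sc]] - 1), by = bin_size)
    data.table(scaffold = sc, bin_start = starts,
               bin_end = pmin(starts + bin_size, lengths[[sc]]))
  }))
  grid[, n_pairs := 0L]
  if (nrow(pairs)) {
    cnt <- pairs[, .(scaffold = scaffold1, pos = start1)][
      , .(cnt = .N), by = .(scaffold, bin_start = floor(pos / bin_size) * bin_size)]
    grid[cnt, n_pairs := i.cnt, on = c("scaffold", "bin_start")]
  }
  grid[, n_pairs := as.integer(n_pairs)]
  grid[]
}

#' Per-scaffold and assembly-level consistency summary
#'
#' For each scaffold: whether it is long enough to assess (length >=
#' `lib$upper`), whether it is fully consistent (at least one window and no
#' non-CONSISTENT discrepancy), the bases under the union of CONSISTENT
#' window extents, and per-class discrepancy counts. Assembly-level
#' aggregates are reported against both denominators (all scaffolds, and
#' assessable scaffolds only).
#'
#' @param lengths Named numeric vector of scaffold lengths.
#' @param discrepancies A merged, classified discrepancy table.
#' @param lib A [library_model()].
#' @return A list: `per_scaffold` (data.table) and `summary` (data.table of
#'   assembly-level aggregates).
#' @export
consistency_summary <- function(lengths, discrepancies, lib) {
  d <- as.data.table(discrepancies)
  kinds <- c("CONSISTENT", "INSERTION", "DELETION", "MISORIENTATION", "BREAK", "NEWJOIN")
  per <- data.table(scaffold = names(lengths), length = as.numeric(lengths))
  per[, assessable := length >= lib$upper]
  for (k in kinds) {
    cnt <- if (nrow(d)) d[kind == k, .N, by = scaffold] else NULL
    per[, (paste0("n_", tolower(k))) := 0L]
    if (!is.null(cnt) && nrow(cnt))
      per[cnt, (paste0("n_", tolower(k))) := i.N, on = "scaffold"]
  }
  per[, consistent_bases := 0]
  if (nrow(d)) {
    cb <- d[kind == "CONSISTENT",
            {
              cl <- clip_intervals(start, end, lengths[[.BY$scaffold]])
              .(cb = interval_union_length(cl$start, cl$end))
            }, by = scaffold]
    if (nrow(cb)) per[cb, consistent_bases := i.cb, on = "scaffold"]
  }
  per[, pct_consistent_bases := 100 * consistent_bases / length]
  per[, fully_consistent := n_consistent >= 1L &
        (n_insertion + n_deletion + n_misorientation + n_break + n_newjoin) == 0L]
  agg <- data.table(
    n_scaffolds = nrow(per),
    n_assessable = sum(per$assessable),
    pct_scaffolds_consistent_all = 100 * mean(per$fully_consistent),
    pct_scaffolds_consistent_assessable =
      if (any(per$assessable)) 100 * mean(per$fully_consistent[per$assessable]) else NA_real_,
    pct_bases_consistent_all = 100 * sum(per$consistent_bases) / sum(per$length),
    pct_bases_consistent_assessable =
      if (any(per$assessable))
        100 * sum(per$consistent_bases[per$assessable]) / sum(per$length[per$assessable])
      else NA_real_
  )
  list(per_scaffold = per[], summary = agg)
}

#' Assess an assembly with cleaned mate pairs
#'
#' Runs the full assessment: window scan, classification, BREAK filtering,
#' merging of same-class overlapping calls, consistency summary and
#' coverage binning.
#'
#' @param pairs A cleaned pair table (assessment profile).
#' @param lengths Named numeric vector of scaffold lengths.
#' @param lib A [library_model()].
#' @param params An [assess_params()].
#' @param bin_size Coverage bin width (default 100,000 bp).
#' @return A list: `windows`, `discrepancies` (merged), `consistency`
#'   (list of `per_scaffold`, `summary`), `coverage`.
#' @export
assess_assembly <- function(pairs, lengths, lib = library_model(),
                            params = assess_params(), bin_size = 100000) {
  w <- scan_windows(pairs, params)
  d <- classify_windows(w, lib)
  d <- detect_breaks(d, lengths, lib)
  d <- merge_discrepancies(d)
  list(windows = w, discrepancies = d,
       consistency = consistency_summary(lengths, d, lib),
       coverage = coverage_bins(pairs, lengths, bin_size))
}
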