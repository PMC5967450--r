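## Brute-force reference implementations used to cross-check the package's
## optimised code paths on small random instances. These share no code with
## the implementation: plain data.frames, exhaustive enumeration, explicit
## subset checks.

## exhaustive driver/follower window enumeration: every (read-start,
## mate-start) anchor pair defines a candidate rectangle; candidates are
## deduplicated and non-maximal sets removed by direct subset comparison.
## Returns the aggregate tuple table (one row per maximal window).
oracle_scan <- function(pairs, params) {
  rows <- rbind(
    data.frame(pair = pairs$pair_id, scaf = pairs$scaffold1, s = pairs$start1,
               e = pairs$end1, mscaf = pairs$scaffold2, ms = pairs$start2,
               me = pairs$end2, stringsAsFactors = FALSE),
    data.frame(pair = pairs$pair_id, scaf = pairs$scaffold2, s = pairs$start2,
               e = pairs$end2, mscaf = pairs$scaffold1, ms = pairs$start1,
               me = pairs$end1, stringsAsFactors = FALSE)
  )
  rows$rid <- seq_len(nrow(rows))
  dmax <- params$driver_max; fmax <- params$follower_max; msup <- params$min_support

  maximal_only <- function(sets) {
    sets <- sets[!duplicated(vapply(sets, paste, "", collapse = ","))]
    if (length(sets) < 2L) return(sets)
    drop <- vapply(seq_along(sets), function(i) {
      any(vapply(seq_along(sets), function(j) {
        j != i && length(sets[[j]]) > length(sets[[i]]) &&
          all(sets[[i]] %in% sets[[j]])
      }, logical(1)))
    }, logical(1))
    sets[!drop]
  }

  win_sets <- list()
  grp <- unique(rows[, c("scaf", "mscaf")])
  for (gi in seq_len(nrow(grp))) {
    gr <- rows[rows$scaf == grp$scaf[gi] & rows$mscaf == grp$mscaf[gi], , drop = FALSE]
    sets <- list()
    for (a in unique(gr$s)) for (b in unique(gr$ms)) {
      memb <- which(gr$s >= a & gr$s < a + dmax & gr$ms >= b & gr$ms < b + fmax)
      if (length(unique(gr$pair[memb])) >= msup)
        sets <- c(sets, list(sort(gr$rid[memb])))
    }
    win_sets <- c(win_sets, maximal_only(sets))
  }
  used <- unique(unlist(win_sets))

  absent_sets <- list()
  left <- rows[!rows$rid %in% used, , drop = FALSE]
  for (sc in unique(left$scaf)) {
    l <- left[left$scaf == sc, , drop = FALSE]
    sets <- list()
    for (a in unique(l$s)) {
      memb <- which(l$s >= a & l$s < a + dmax)
      if (length(unique(l$pair[memb])) >= msup)
        sets <- c(sets, list(sort(l$rid[memb])))
    }
    absent_sets <- c(absent_sets, maximal_only(sets))
  }

  tuple <- function(ids, absent) {
    r <- rows[match(ids, rows$rid), , drop = FALSE]
    data.frame(scaffold = r$scaf[1], driver_start = min(r$s), driver_end = max(r$e),
               follower_scaffold = if (absent) NA_character_ else r$mscaf[1],
               follower_start = if (absent) NA_real_ else min(r$ms),
               follower_end = if (absent) NA_real_ else max(r$me),
               support = length(unique(r$pair)), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(lapply(win_sets, tuple, absent = FALSE),
                          lapply(absent_sets, tuple, absent = TRUE)))
  if (is.null(out))
    out <- data.frame(scaffold = character(), driver_start = numeric(),
                      driver_end = numeric(), follower_scaffold = character(),
                      follower_start = numeric(), follower_end = numeric(),
                      support = integer(), stringsAsFactors = FALSE)
  out[order(out$scaffold, out$driver_start, out$driver_end, out$follower_scaffold,
            out$follower_start, out$support, na.last = TRUE), , drop = FALSE]
}

## canonicalize scan_windows() output to the oracle's tuple form
scan_tuples <- function(windows) {
  w <- as.data.frame(windows[, c("scaffold", "driver_start", "driver_end",
                                 "follower_scaffold", "follower_start",
                                 "follower_end", "support")])
  w[order(w$scaffold, w$driver_start, w$driver_end, w$follower_scaffold,
          w$follower_start, w$support, na.last = TRUE), , drop = FALSE]
}

## per-base depth by direct counting (scaffolds assumed small)
oracle_depth_regions <- function(placements, len, depth_max) {
  counts <- integer(len)
  for (i in seq_len(nrow(placements))) {
    idx <- (placements$start[i] + 1):placements$end[i]
    counts[idx] <- counts[idx] + 1L
  }
  deep <- counts > depth_max
  if (!any(deep)) return(data.frame(start = numeric(), end = numeric()))
  r <- rle(deep)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

## duplicate removal by explicit grouping
oracle_dedup_ids <- function(pairs) {
  key <- paste(pairs$scaffold1, pairs$start1, pairs$end1, pairs$strand1,
               pairs$scaffold2, pairs$start2, pairs$end2, pairs$strand2)
  sort(unname(vapply(split(pairs$pair_id, key), min, "")))
}

oracle_n50 <- function(lengths, frac = 0.5) {
  l <- sort(lengths, decreasing = TRUE)
  tot <- sum(l); cum <- 0
  for (x in l) { cum <- cum + x; if (cum >= frac * tot) return(x) }
}

oracle_union_length <- function(start, end, len) {
  covered <- logical(len)
  for (i in seq_along(start)) {
    s <- max(start[i], 0); e <- min(end[i], len)
    if (s < e) covered[(s + 1):e] <- TRUE
  }
  sum(covered)
}

oracle_bins <- function(pos, len, bin) {
  n_bins <- ceiling(len / bin)
  counts <- integer(n_bins)
  for (p in pos) {
    b <- floor(p / bin) + 1
    counts[b] <- counts[b] + 1L
  }
  counts
}

## random pair instance for the scan oracle (coordinates kept integer)
rand_pair_instance <- function(n_pairs, span_max = 60000, two_scaffolds = TRUE,
                               read_len = 250) {
  scafs <- if (two_scaffolds) c("sA", "sB") else "sA"
  sc1 <- sample(scafs, n_pairs, replace = TRUE)
  sc2 <- sample(scafs, n_pairs, replace = TRUE)
  pl <- rbind(
    placement_table(sprintf("q%03d", 1:n_pairs), 1L, sc1,
                    st1 <- sample.int(span_max, n_pairs), st1 + read_len,
                    sample(c("+", "-"), n_pairs, TRUE)),
    placement_table(sprintf("q%03d", 1:n_pairs), 2L, sc2,
                    st2 <- sample.int(span_max, n_pairs), st2 + read_len,
                    sample(c("+", "-"), n_pairs, TRUE))
  )
  make_pairs(pl)$pairs
}
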