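## Post-alignment cleaning of mate-pair placements, in the fixed order
## multi-mapper removal -> duplicate removal -> repeat-depth filter ->
## orphan/orientation filter, followed by insert-size estimation. Each
## filter is idempotent; clean_placements() composes them and logs the
## record count surviving each stage.

#' Remove multi-mapped placements
#'
#' Drops every placement reported to map to more than one equally good
#' location (`n_hits > 1`). Repeat-derived reads carry no usable positional
#' information for 38-kb jump analysis and are removed outright.
#'
#' @param placements A placement table.
#' @return The placements with `n_hits == 1`.
#' @export
remove_multimapped <- function(placements) {
  placements[n_hits == 1L]
}

#' Remove duplicate pairs
#'
#' Among pairs sharing scaffold, both outer coordinates and both strands
#' (the positional criterion standard duplicate marking uses), exactly one
#' representative is kept: the lexicographically smallest `pair_id`.
#' Pairs are stored in canonical placement order, so the criterion is
#' symmetric in the two mates.
#'
#' @param pairs A pair table ([make_pairs()]).
#' @return The de-duplicated pair table.
#' @export
remove_duplicates <- function(pairs) {
  if (!nrow(pairs)) return(pairs)
  keyed <- pairs[order(pair_id)]
  keyed[!duplicated(keyed[, .(scaffold1, start1, end1, strand1,
                              scaffold2, start2, end2, strand2)])][order(pair_id)]
}

## per-base depth profile of a set of placements on one scaffold, as a
## step function: data.table(start, end, depth) over maximal constant runs
depth_profile <- function(start, end) {
  ev <- data.table(pos = c(start, end), d = rep(c(1L, -1L), each = length(start)))
  ev <- ev[, .(d = sum(d)), by = pos][order(pos)]
  ev[, depth := cumsum(d)]
  data.table(start = ev$pos[-nrow(ev)], end = ev$pos[-1],
             depth = ev$depth[-nrow(ev)])[start < end]
}

#' Repeat-depth filter
#'
#' Computes exact per-base read depth from the placements, reports every
#' maximal interval whose depth exceeds `depth_max`, and removes any
#' placement overlapping such an interval together with its mate. This is
#' the repeat screen: 38-kb-scale repeats shared across the genome pile
#' mate-pair reads into deep stacks that would otherwise generate spurious
#' window evidence.
#'
#' @param placements A placement table.
#' @param depth_max Maximum tolerated depth (default 5).
#' @param lengths Optional named scaffold lengths for bound checking.
#' @return A list: `placements` (surviving rows) and `removed_regions`
#'   (data.table of `scaffold`, `start`, `end`, `depth`).
#' @export
depth_filter <- function(placements, depth_max = 5L, lengths = NULL) {
  validate_placements(placements, lengths)
  if (!nrow(placements))
    return(list(placements = placements,
                removed_regions = data.table(scaffold = character(), start = numeric(),
                                             end = numeric(), depth = integer())))
  deep <- placements[, {
    pr <- depth_profile(start, end)
    pr <- pr[depth > depth_max]
    if (nrow(pr)) {
      ## merge adjacent deep runs into maximal intervals; report peak depth
      grp <- cumsum(c(1L, as.integer(pr$start[-1] > pr$end[-nrow(pr)])))
      pr[, .(start = min(start), end = max(end), depth = max(depth)), by = grp][, !"grp"]
    } else data.table(start = numeric(), end = numeric(), depth = integer())
  }, by = scaffold]
  if (!nrow(deep))
    return(list(placements = placements, removed_regions = deep))
  setkey(deep, scaffold, start, end)
  hit <- foverlaps(
    placements[, .(read_id, pair_id, scaffold, start, end)],
    deep, by.x = c("scaffold", "start", "end"), nomatch = NULL
  )
  bad_pairs <- unique(hit$pair_id)
  list(placements = placements[!pair_id %in% bad_pairs],
       removed_regions = deep[])
}

#' Orphan / orientation filter
#'
#' Drops pairs unusable for the chosen task. Both profiles drop orphans
#' (reads whose mate is unmapped -- orphans never reach this function as
#' pairs, so the function simply takes the paired table). The
#' `"scaffolding"` profile additionally drops same-scaffold pairs whose
#' orientation is not the expected library geometry, because scaffolding
#' needs clean distance+orientation constraints. The `"assessment"` profile
#' keeps them: wrongly oriented pairs are the signal a mis-oriented
#' assembly is detected by.
#'
#' @param pairs A pair table.
#' @param profile `"assessment"` (default) or `"scaffolding"`.
#' @return The filtered pair table.
#' @export
pair_filter <- function(pairs, profile = c("assessment", "scaffolding")) {
  profile <- match.arg(profile)
  if (profile == "scaffolding")
    pairs <- pairs[!same_scaffold | orientation == "expected"]
  pairs
}

#' Clean placements end to end
#'
#' Composes the post-alignment filters in their fixed order: remove
#' multi-mappers, form pairs (shedding orphans), remove positional
#' duplicates, apply the repeat-depth filter, then the profile-specific
#' orphan/orientation filter. Per-stage record counts are returned as the
#' cleaning log.
#'
#' @param placements A placement table (raw mapped reads).
#' @param profile `"assessment"` or `"scaffolding"` (see [pair_filter()]).
#' @param depth_max Depth threshold for the repeat filter (default 5).
#' @param geometry Library read geometry, `"outward"` or `"inward"`.
#' @param lengths Optional named scaffold lengths.
#' @return A list: `pairs` (cleaned pair table), `removed_regions` (deep
#'   repeat intervals), `log` (data.table of stage, reads, pairs).
#' @export
clean_placements <- function(placements, profile = c("assessment", "scaffolding"),
                             depth_max = 5L, geometry = c("outward", "inward"),
                             lengths = NULL) {
  profile <- match.arg(profile)
  geometry <- match.arg(geometry)
  log <- list(data.table(stage = "input", reads = nrow(placements), pairs = NA_integer_))
  pl <- remove_multimapped(placements)
  log <- c(log, list(data.table(stage = "unique_mapping", reads = nrow(pl),
                                pairs = NA_integer_)))
  pr <- make_pairs(pl, geometry = geometry)
  log <- c(log, list(data.table(stage = "paired", reads = 2L * nrow(pr$pairs),
                                pairs = nrow(pr$pairs))))
  pairs <- remove_duplicates(pr$pairs)
  log <- c(log, list(data.table(stage = "deduplicated", reads = 2L * nrow(pairs),
                                pairs = nrow(pairs))))
  df <- depth_filter(pairs_to_placements(pairs), depth_max = depth_max, lengths = lengths)
  pairs <- pairs[pair_id %in% unique(df$placements$pair_id)]
  log <- c(log, list(data.table(stage = sprintf("depth_le_%d", as.integer(depth_max)),
                                reads = 2L * nrow(pairs), pairs = nrow(pairs))))
  pairs <- pair_filter(pairs, profile = profile)
  log <- c(log, list(data.table(stage = profile, reads = 2L * nrow(pairs),
                                pairs = nrow(pairs))))
  list(pairs = pairs, removed_regions = df$removed_regions, log = rbindlist(log))
}

#' Estimate the insert-size distribution from mapped pairs
#'
#' Fits the library model from the outer-distance spans of same-scaffold,
#' expected-orientation pairs falling inside `fit_window`. The window
#' (default 10--80 kb) excludes chimeric ultra-long spans and short-range
#' artefacts from corrupting the moments of a unimodal ~38-kb library.
#'
#' @param pairs A pair table (cleaned; assessment profile is fine).
#' @param fit_window Numeric length-2: spans (bp) used for fitting.
#' @param min_pairs Minimum qualifying pairs required (default 100).
#' @return A [library_model()] with `mu` = mean, `sigma` = sd of the
#'   qualifying spans.
#' @export
estimate_insert_distribution <- function(pairs, fit_window = c(10000, 80000),
                                         min_pairs = 100L) {
  q <- pairs[same_scaffold & orientation == "expected" &
               span >= fit_window[1] & span <= fit_window[2]]
  if (nrow(q) < min_pairs)
    stop(sprintf("only %d qualifying pairs (need >= %d) to estimate the insert distribution",
                 nrow(q), min_pairs))
  s <- sd(q$span)
  if (!is.finite(s) || s <= 0)
    stop("degenerate insert-size distribution (sd = 0); refusing zero-width thresholds")
  library_model(mean(q$span), s)
}
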