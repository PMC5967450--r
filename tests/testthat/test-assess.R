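test_that("the driver/follower scan honours the support threshold", {
  ## 5 reads within 8 kb whose mates sit within 15 kb downstream: one window
  at <- c(0, 2000, 4000, 6000, 7900)
  pl <- do.call(rbind, Map(mk_span_pair, sprintf("p%d", 1:5), 37725, at))
  pairs <- make_pairs(pl)$pairs
  w <- scan_windows(pairs)
  ## every pair contributes both read sides, so the same five pairs form one
  ## forward window (drivers left, followers right) and its mirror image
  expect_equal(nrow(w), 2L)
  expect_equal(w$support, c(5L, 5L))
  expect_equal(w$driver_start, c(0, 37475))
  expect_equal(w$follower_scaffold, c("s1", "s1"))
  expect_equal(w$median_span, c(37725, 37725))
  expect_equal(w$orientation_consensus, c("expected", "expected"))

  ## 4 reads only: no window (and too few for follower-absent evidence)
  w4 <- scan_windows(make_pairs(pl[pl$pair_id != "p5"])$pairs)
  expect_equal(nrow(w4), 0L)

  ## reads spread over >10 kb cannot form one driver window
  at_wide <- c(0, 4000, 8000, 12000, 16000)
  pl_wide <- do.call(rbind, Map(mk_span_pair, sprintf("p%d", 1:5), 37725, at_wide))
  w_wide <- scan_windows(make_pairs(pl_wide)$pairs)
  expect_true(all(w_wide$support < 5L) || nrow(w_wide) == 0L)
})

test_that("window scan equals exhaustive maximal-set enumeration", {
  set.seed(301)
  sizes <- c(sample(5:40, 16, replace = TRUE), 60, 80, 100)
  for (n in sizes) {
    pairs <- rand_pair_instance(n)
    ms <- sample(c(2L, 3L, 5L), 1)
    dm <- sample(c(3000, 10000), 1)
    params <- assess_params(min_support = ms, driver_max = dm, follower_max = 2 * dm)
    got <- scan_tuples(scan_windows(pairs, params))
    want <- oracle_scan(pairs, params)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = sprintf("n=%d ms=%d dm=%d", n, ms, dm))
  }
})

test_that("classification follows the fixed decision order", {
  lib <- library_model(37725, 4200)
  base <- data.table::data.table(
    scaffold = "s1", driver_start = 0, driver_end = 9000,
    follower_scaffold = "s1", follower_start = 40000, follower_end = 55000,
    support = 8L, median_span = 37725, orientation_consensus = "expected",
    members = list("p"))
  w <- data.table::rbindlist(list(
    base,                                                    # CONSISTENT
    within(base, median_span <- 55000),                      # INSERTION (>50 kb)
    within(base, median_span <- 22000),                      # DELETION  (<25 kb)
    within(base, {orientation_consensus <- "reversed"; median_span <- 40000}),
    within(base, follower_scaffold <- "s2"),                 # NEWJOIN
    within(base, {follower_scaffold <- NA_character_
                  follower_start <- NA_real_; follower_end <- NA_real_})  # BREAK
  ))
  d <- classify_windows(w, lib)
  expect_equal(d$kind, c("CONSISTENT", "INSERTION", "DELETION", "MISORIENTATION",
                         "NEWJOIN", "BREAK"))
  ## reversed consensus outranks an aberrant span
  w_both <- within(base, {orientation_consensus <- "reversed"; median_span <- 60000})
  expect_equal(classify_windows(w_both, lib)$kind, "MISORIENTATION")
  ## spans at the exact boundaries stay consistent (strict inequalities)
  expect_equal(classify_windows(within(base, median_span <- lib$upper), lib)$kind,
               "CONSISTENT")
  expect_equal(classify_windows(within(base, median_span <- lib$lower), lib)$kind,
               "CONSISTENT")
})

test_that("BREAK calls respect the scaffold-end exemption and consistency guard", {
  lib <- library_model(37725, 4200)
  lens <- c(s1 = 1e6)
  mk_break <- function(s, e) data.table::data.table(
    scaffold = "s1", start = s, end = e, kind = "BREAK", support = 6L,
    median_span = NA_real_, follower_scaffold = NA_character_,
    follower_start = NA_real_, follower_end = NA_real_,
    orientation_consensus = NA_character_)
  ## driver 10 kb from the scaffold end: exempt
  expect_equal(nrow(detect_breaks(mk_break(990000 - 10000, 990000), lens, lib)), 0L)
  expect_equal(nrow(detect_breaks(mk_break(10000, 18000), lens, lib)), 0L)
  ## mid-scaffold: kept
  mid <- mk_break(500000, 508000)
  expect_equal(detect_breaks(mid, lens, lib), mid)
  ## overlapped by a CONSISTENT window: suppressed
  cons <- data.table::data.table(
    scaffold = "s1", start = 495000, end = 540000, kind = "CONSISTENT",
    support = 10L, median_span = 37725, follower_scaffold = "s1",
    follower_start = 530000, follower_end = 540000,
    orientation_consensus = "expected")
  expect_equal(detect_breaks(rbind(cons, mid), lens, lib)$kind, "CONSISTENT")
})

test_that("a simulated chimera is flagged near the junction, an intact scaffold is not", {
  lib <- library_model()
  g <- cached("g1m_pair", sim_genome(1e6, n_families = 0L, copies = 0L, seed = 9))
  ## chimera: two half-megabase regions that do not belong together
  chim <- inject_errors(g, errors = data.frame(kind = "misjoin", start = 250000,
                                               size = NA, start2 = 750000),
                        fragments = 500000)
  sim <- simulate_matepairs(g, chim, lib, seed = 10)
  cl <- clean_placements(sim$placements, "assessment", lengths = chim$lengths)
  res <- assess_assembly(cl$pairs, chim$lengths, lib)
  flagged <- res$discrepancies[kind %in% c("BREAK", "NEWJOIN")]
  expect_true(nrow(flagged) > 0)
  ## every junction is hit within one insert upper bound
  rec <- error_recovery(res$discrepancies, chim$truth, lib)
  expect_true(all(rec$per_truth$detected))

  ## error-free control: no breaks, no joins
  intact <- cached("asm1m_pair", inject_errors(g))
  sim0 <- simulate_matepairs(g, intact, lib, seed = 11)
  cl0 <- clean_placements(sim0$placements, "assessment", lengths = intact$lengths)
  res0 <- assess_assembly(cl0$pairs, intact$lengths, lib)
  expect_equal(nrow(res0$discrepancies[kind %in% c("BREAK", "NEWJOIN")]), 0L)
})

test_that("every window yields exactly one discrepancy class", {
  lib <- library_model()
  g <- cached("g1m_pair", sim_genome(1e6, n_families = 0L, copies = 0L, seed = 9))
  asm <- cached("asm1m_pair", inject_errors(g))
  sim <- simulate_matepairs(g, asm, lib, seed = 12)
  cl <- clean_placements(sim$placements, "assessment", lengths = asm$lengths)
  w <- scan_windows(cl$pairs)
  d <- classify_windows(w, lib)
  expect_equal(nrow(d), nrow(w))
  expect_true(all(d$kind %in% c("CONSISTENT", "INSERTION", "DELETION",
                                "MISORIENTATION", "BREAK", "NEWJOIN")))
})

test_that("coverage binning counts leftmost pair coordinates per bin", {
  pl <- do.call(rbind, Map(mk_span_pair, c("p1", "p2", "p3"), 30000,
                           c(10000, 150000, 160000)))
  pairs <- make_pairs(pl)$pairs
  bins <- coverage_bins(pairs, c(s1 = 200000), bin_size = 100000)
  expect_equal(bins$n_pairs, c(1L, 2L))
  expect_equal(bins$bin_end, c(100000, 200000))

  ## empty input: zeros, partial final bin included
  bins0 <- coverage_bins(pairs[0], c(s1 = 250000), bin_size = 100000)
  expect_equal(bins0$n_pairs, c(0L, 0L, 0L))
  expect_equal(bins0$bin_end[3], 250000)

  ## brute-force binning oracle
  set.seed(302)
  for (i in 1:10) {
    n <- sample(20:100, 1)
    at <- sample(0:900000, n)
    pl <- do.call(rbind, Map(mk_span_pair, sprintf("p%03d", 1:n), 30000, at))
    pairs <- make_pairs(pl)$pairs
    bins <- coverage_bins(pairs, c(s1 = 1e6), bin_size = 100000)
    expect_equal(bins$n_pairs, oracle_bins(at, 1e6, 100000), info = paste("instance", i))
  }
})

test_that("consistency summary measures bases under consistent windows", {
  lib <- library_model()
  ## one scaffold fully tiled by consistent windows
  d <- data.table::data.table(
    scaffold = "s1", start = c(0, 300000, 600000), end = c(400000, 700000, 1e6),
    kind = "CONSISTENT", support = 10L, median_span = 37725,
    follower_scaffold = "s1", n_windows = 1L)
  cs <- consistency_summary(c(s1 = 1e6, tiny = 20000), d, lib)
  s1 <- cs$per_scaffold[scaffold == "s1"]
  expect_equal(s1$pct_consistent_bases, 100)
  expect_true(s1$fully_consistent)
  ## a scaffold shorter than the upper span is not assessable
  expect_false(cs$per_scaffold[scaffold == "tiny"]$assessable)
  expect_equal(cs$summary$n_assessable, 1L)
  expect_equal(cs$summary$pct_scaffolds_consistent_assessable, 100)
  expect_equal(cs$summary$pct_bases_consistent_assessable, 100)

  ## a non-consistent call breaks the fully-consistent flag
  d2 <- rbind(d, data.table::data.table(
    scaffold = "s1", start = 5e5, end = 5.1e5, kind = "DELETION", support = 6L,
    median_span = 20000, follower_scaffold = "s1", n_windows = 1L))
  cs2 <- consistency_summary(c(s1 = 1e6), d2, lib)
  expect_false(cs2$per_scaffold$fully_consistent[1])

  ## interval-union base counting equals the brute-force union
  set.seed(303)
  for (i in 1:10) {
    n <- sample(3:30, 1)
    s <- sample(0:90000, n); e <- s + sample(1000:30000, n, TRUE)
    dd <- data.table::data.table(scaffold = "s", start = s, end = pmin(e, 1e5),
                                 kind = "CONSISTENT", support = 5L,
                                 median_span = 37725, follower_scaffold = "s",
                                 n_windows = 1L)
    cs <- consistency_summary(c(s = 1e5), dd, lib)
    expect_equal(cs$per_scaffold$consistent_bases,
                 oracle_union_length(s, pmin(e, 1e5), 1e5), info = paste("instance", i))
  }
})

test_that("overlapping same-class calls merge into maximal intervals", {
  d <- data.table::data.table(
    scaffold = c("s1", "s1", "s1", "s1"),
    start = c(0, 5000, 20000, 5000), end = c(10000, 15000, 30000, 9000),
    kind = c("DELETION", "DELETION", "DELETION", "INSERTION"),
    support = c(5L, 9L, 6L, 7L), median_span = c(20000, 21000, 22000, 60000),
    follower_scaffold = "s1", follower_start = NA_real_, follower_end = NA_real_,
    orientation_consensus = "expected")
  m <- merge_discrepancies(d)
  del <- m[kind == "DELETION"]
  expect_equal(nrow(del), 2L)              # [0,15000) merged; [20000,30000) apart
  expect_equal(del$start, c(0, 20000))
  expect_equal(del$end, c(15000, 30000))
  expect_equal(del$support, c(9L, 6L))     # max support of merged calls
  expect_equal(nrow(m[kind == "INSERTION"]), 1L)  # different class never merges
})
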