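test_that("genome generation is seeded, GC-controlled and repeat-annotated", {
  g1 <- sim_genome(1e6, n_families = 2L, copies = 5L, seed = 5)
  g2 <- sim_genome(1e6, n_families = 2L, copies = 5L, seed = 5)
  expect_identical(g1$seq, g2$seq)
  expect_identical(g1$repeats, g2$repeats)

  gc <- sum(strsplit(g1$seq, "")[[1]] %in% c("G", "C")) / g1$length
  expect_lt(abs(gc - 0.46), 0.01)

  ## annotated repeat copies are near-identical within a family
  r <- g1$repeats[g1$repeats$family == 1L]
  c1 <- substring(g1$seq, r$start[1] + 1, r$end[1])
  c2 <- substring(g1$seq, r$start[2] + 1, r$end[2])
  ident <- mean(strsplit(c1, "")[[1]] == strsplit(c2, "")[[1]])
  expect_gt(ident, 0.95)
  ## and are placed where the annotation says (exact substring recovery)
  expect_equal(nchar(c1), 5000L)
  expect_error(sim_genome(1e5, n_families = 5L, copies = 20L), "half the genome")
})

test_that("error injection edits the assembly exactly as specified", {
  g <- cached("g1m_sim", sim_genome(1e6, n_families = 0L, copies = 0L, seed = 31))
  ## empty spec: assembly equals genome
  asm0 <- inject_errors(g)
  expect_identical(unname(asm0$records[1]), g$seq)
  expect_equal(nrow(asm0$truth), 0L)

  ## fragmentation reconstructs the genome in order and records adjacencies
  frag <- inject_errors(g, fragments = c(300000, 700000))
  expect_identical(paste(frag$records, collapse = ""), g$seq)
  expect_equal(frag$adjacency$a_id, c("scf_001", "scf_002"))
  expect_equal(frag$adjacency$b_id, c("scf_002", "scf_003"))

  ## deletion, insertion, inversion against a substring oracle
  errs <- data.frame(kind = c("deletion", "insertion", "inversion"),
                     start = c(100000, 400000, 800000),
                     size = c(12000, 15000, 50000), start2 = NA)
  asm <- inject_errors(g, errors = errs)
  seg <- function(s, e) substring(g$seq, s + 1, e)
  want <- paste0(seg(0, 100000), seg(112000, 400000),
                 seg(400000, 415000), seg(400000, 415000),
                 seg(415000, 800000), revcomp(seg(800000, 850000)),
                 seg(850000, 1000000))
  expect_identical(unname(asm$records[1]), want)
  expect_equal(asm$lengths[[1]], 1e6 - 12000 + 15000)
  tr <- asm$truth
  expect_equal(tr[tr$kind == "deletion"]$start, 100000)
  expect_equal(tr[tr$kind == "deletion"]$end, 100000)     # junction point
  expect_equal(tr[tr$kind == "insertion"]$start, 403000)  # second copy, after -12 kb shift
  expect_equal(tr[tr$kind == "insertion"]$end, 418000)
  expect_equal(tr[tr$kind == "inversion"]$end - tr[tr$kind == "inversion"]$start, 50000)

  ## misjoin swaps tails between two scaffolds
  mj <- inject_errors(g, errors = data.frame(kind = "misjoin", start = 200000,
                                             size = NA, start2 = 600000),
                      fragments = 500000)
  expect_identical(unname(mj$records[["scf_001"]]),
                   paste0(seg(0, 200000), seg(600000, 1000000)))
  expect_identical(unname(mj$records[["scf_002"]]),
                   paste0(seg(500000, 600000), seg(200000, 500000)))
  expect_equal(nrow(mj$truth[mj$truth$kind == "misjoin"]), 2L)
  expect_equal(mj$truth[scaffold == "scf_001"]$start, 200000)
  expect_equal(mj$truth[scaffold == "scf_002"]$start, 100000)

  ## overlapping edits are refused
  expect_error(inject_errors(g, errors = data.frame(
    kind = c("deletion", "inversion"), start = c(100000, 105000),
    size = c(12000, 20000), start2 = NA)), "unmodified region")
})

test_that("mate-pair simulation matches the library design arithmetic", {
  lib <- library_model()
  g <- fixture_genome()
  asm <- fixture_clean_assembly()
  sim <- cached("sim10_fix", simulate_matepairs(g, asm, lib, seed = 51))
  ## 0.75x of 10 Mb at 2 x 250 bp = 15,000 pairs
  expect_equal(nrow(sim$truth), 15000L)
  ## implied physical coverage ~56x, comfortably above 50x
  expect_gt(nrow(sim$truth) * lib$mu / g$length, 50)
  ## determinism
  sim2 <- simulate_matepairs(g, asm, lib, seed = 51)
  expect_identical(sim2$placements, sim$placements)

  ## empirical insert moments match the request within 3 standard errors
  expect_lt(abs(mean(sim$truth$insert) - lib$mu), 3 * lib$sigma / sqrt(15000) + 0.5)
  expect_lt(abs(sd(sim$truth$insert) - lib$sigma),
            3 * lib$sigma / sqrt(2 * 15000) + 0.5)

  ## error-free assembly: every complete pair is concordant
  pairs <- make_pairs(sim$placements)$pairs
  same <- pairs[pairs$same_scaffold == TRUE]
  expect_true(all(same$orientation == "expected"))
  expect_true(all(same$span >= 500))        # truncation bound: 2 x read_len
})

test_that("repeat-derived reads multi-map and duplicates are flagged", {
  lib <- library_model()
  g <- cached("g1m_rep", sim_genome(1e6, n_families = 1L, copies = 6L, seed = 61))
  asm <- inject_errors(g)
  sim <- simulate_matepairs(g, asm, lib, seed = 62, dup_rate = 0.1)
  ## duplicated pairs: same coordinates, distinct id, removed by deduplication
  expect_equal(nrow(sim$placements[grepl("d$", pair_id)]) > 0, TRUE)
  pairs <- make_pairs(sim$placements)$pairs
  dd <- remove_duplicates(pairs)
  expect_false(any(grepl("d$", dd$pair_id)))

  ## reads fully inside an annotated repeat copy carry the copy count
  rp <- g$repeats
  pl <- sim$placements
  inside <- rep(FALSE, nrow(pl))
  for (i in seq_len(nrow(rp)))
    inside <- inside | (pl$start >= rp$start[i] & pl$end <= rp$end[i])
  expect_true(all(pl$n_hits[inside] == 6L))
  expect_true(all(pl$n_hits[!inside] == 1L))

  ## an insertion duplicates sequence: reads inside it map twice
  dupasm <- inject_errors(cached("g1m_sim", sim_genome(1e6, n_families = 0L,
                                                       copies = 0L, seed = 31)),
                          errors = data.frame(kind = "insertion", start = 500000,
                                              size = 20000, start2 = NA))
  sim_d <- simulate_matepairs(cached("g1m_sim", sim_genome(1e6, n_families = 0L,
                                                           copies = 0L, seed = 31)),
                              dupasm, lib, seed = 63)
  pl_d <- sim_d$placements
  in_dup <- pl_d$start >= 500000 & pl_d$end <= 520000 & pl_d$n_hits == 2L
  expect_gt(sum(in_dup), 0)
})

test_that("pairs spanning injected errors carry the discordant signal", {
  lib <- library_model()
  g <- cached("g1m_sim", sim_genome(1e6, n_families = 0L, copies = 0L, seed = 31))
  del <- inject_errors(g, errors = data.frame(kind = "deletion", start = 500000,
                                              size = 15000, start2 = NA))
  sim <- simulate_matepairs(g, del, lib, seed = 64)
  pairs <- make_pairs(sim$placements)$pairs
  crossing <- pairs[pairs$start1 < 500000 & pairs$end2 > 500000]
  ## spans across the deleted segment shrink by its size
  expect_gt(nrow(crossing), 10)
  expect_lt(abs(median(crossing$span) - (lib$mu - 15000)), 2000)

  inv <- inject_errors(g, errors = data.frame(kind = "inversion", start = 500000,
                                              size = 50000, start2 = NA))
  sim_i <- simulate_matepairs(g, inv, lib, seed = 65)
  pairs_i <- make_pairs(sim_i$placements)$pairs
  straddle <- pairs_i[pairs_i$start1 < 500000 & pairs_i$end2 > 500000 &
                        pairs_i$end2 < 550000]
  expect_gt(nrow(straddle), 10)
  expect_true(all(straddle$orientation == "reversed"))
})

test_that("the coverage sweep is seeded and saturates with coverage", {
  sw1 <- cached("sweep_small",
                sweep_coverage(coverages = c(0.2, 0.6), n_reps = 1L, seed = 71,
                               genome_length = 1.5e6, n_contigs = 12L))
  sw2 <- sweep_coverage(coverages = c(0.2, 0.6), n_reps = 1L, seed = 71,
                        genome_length = 1.5e6, n_contigs = 12L)
  expect_identical(as.data.frame(sw1), as.data.frame(sw2))
  expect_gte(sw1$adjacency_recovery[2], sw1$adjacency_recovery[1])
  expect_gte(sw1$error_detection[2], sw1$error_detection[1])
})
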