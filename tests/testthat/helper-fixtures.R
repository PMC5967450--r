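## Shared fixtures, built once per test run. The standard benchmark genome
## is 10 Mb with 5 repeat families x 20 copies x 5 kb at seed 42; smaller
## genomes are used where a test only needs dense window evidence.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

fixture_genome <- function() cached("g10", sim_genome(seed = 42))

## error-free single-scaffold assembly of the standard genome
fixture_clean_assembly <- function() cached("asm0", inject_errors(fixture_genome()))

## a quick placement builder for hand-constructed cases
mk_pl <- function(pair_id, mate, scaffold, start, strand, read_len = 250, n_hits = 1L) {
  placement_table(pair_id, mate, scaffold, start, start + read_len, strand, n_hits)
}

## a same-scaffold pair with given outer span starting at `at` (outward geometry)
mk_span_pair <- function(pair_id, span, at = 0, scaffold = "s1", read_len = 250) {
  rbind(mk_pl(pair_id, 1L, scaffold, at, "-", read_len),
        mk_pl(pair_id, 2L, scaffold, at + span - read_len, "+", read_len))
}
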