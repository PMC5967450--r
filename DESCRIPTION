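Package: matelink
Title: Assembly Assessment and Scaffolding with Long-Insert Mate-Pair Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the independent assessment and improvement of genome
    assemblies using long-insert (fosmid-scale, ~38 kb) mate-pair jumping
    libraries. Implements post-alignment read cleaning (multi-mapper,
    duplicate, repeat-depth and orphan/orientation filters), insert-size
    distribution estimation, a driver/follower sliding-window scan that
    classifies assembly discrepancies (insertions, deletions,
    mis-orientations, mis-joins and candidate new joins), per-assembly
    consistency summaries, and an evidence-based scaffolder that resolves a
    join graph into ordered, oriented scaffold paths with AGP and FASTA
    output and N50/N10 contiguity statistics. A seeded simulator generates
    repeat-bearing genomes, assemblies with injected structural errors, and
    idealized mate-pair placements with known truth, so that every stage of
    the pipeline can be benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
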