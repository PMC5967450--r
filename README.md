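# matelink

Independent assessment and improvement of genome assemblies with
long-insert (fosmid-scale, ~38 kb) mate-pair jumping libraries.

Short-read assemblies of large, repeat-rich genomes (the motivating case is
hexaploid bread wheat, but nothing here is wheat-specific) accumulate
structural errors that short-range data cannot see: missing or duplicated
segments tens of kilobases long, inverted blocks, and chimeric joins.
A jumping library places read pairs a near-constant ~38 kb apart with known
relative orientation, so every mapped pair is an independent measuring stick
laid across the assembly. `matelink` turns those measurements into:

* **assembly assessment** — classified discrepancy calls (insertion,
  deletion, mis-orientation, mis-join, candidate new join) plus per-scaffold
  consistency summaries and coverage profiles;
* **scaffolding** — evidence-backed joins between scaffold ends, resolved
  into ordered and oriented paths, emitted as FASTA + AGP v2.1 with
  N50/N10 statistics;
* **closed-loop benchmarking** — a seeded simulator that builds
  repeat-bearing genomes, derives flawed "assemblies" from them with known
  ground truth, and projects idealized mate-pair placements through the
  flaws, so both engines are testable without any external data or aligner.

## The model

A library is summarised by the insert (outer-distance) distribution
`N(mu, sigma)`, default `mu = 37,725 bp`, `sigma = 4,200 bp`. Spans inside
`mu ± 3·sigma` (≈ 25–50 kb at the defaults) are *consistent*; the band
doubles as the sensitivity floor — flaws smaller than ~3·sigma are
invisible to the method.

Evidence is aggregated with a paired sliding-window filter: at least
**5 unique neighbouring reads** whose starts fit in a *driver* window
**< 10 kb** wide and whose mates co-locate in a *follower* window
**< 20 kb** wide. Each maximal window is classified in a fixed decision
order:

| signal | call |
|---|---|
| follower on another scaffold | `NEWJOIN` |
| follower absent (mates cluster nowhere) | `BREAK` (mis-join) |
| reversed orientation consensus | `MISORIENTATION` |
| median span > `mu + 3·sigma` | `INSERTION` |
| median span < `mu − 3·sigma` | `DELETION` |
| otherwise | `CONSISTENT` |

Before any of this, alignments pass the standard mate-pair hygiene filters:
multi-mappers out, positional duplicates out, reads in regions of depth
greater than 5 out (the repeat screen), orphans out — and, for scaffolding
only, wrongly oriented pairs out (for assessment they are kept: they *are*
the mis-orientation signal).

Scaffold joins require ≥ 5 supporting cross-scaffold pairs, each read
within `mu + 3·sigma` of the scaffold end it points at; an end with
competing candidates keeps the best one only if its support at least
doubles the runner-up, otherwise all are discarded — precision over recall.
Gaps are estimated as the median of `mu − d_a − d_b` over supporting pairs.

## Worked example

Build a 2-Mb genome with repeat families, derive a two-scaffold assembly
carrying known flaws, simulate mate pairs at the library design point, and
assess:

```r
library(matelink)

lib    <- library_model(37725, 4200)
genome <- sim_genome(2e6, n_families = 2, copies = 8, seed = 1)
spec   <- fixture_error_spec(genome, n_scaffolds = 2, n_del = 2, n_ins = 2,
                             n_inv = 1, n_junctions = 2, seed = 1)
assembly <- inject_errors(genome, errors = spec$errors, fragments = spec$fragments)
sim      <- simulate_matepairs(genome, assembly, lib, coverage = 0.75,
                               read_len = 250, seed = 2)
cleaned  <- clean_placements(sim$placements, profile = "assessment",
                             lengths = assembly$lengths)
cleaned$log
#>             stage reads pairs
#> 1:          input  5889    NA
#> 2: unique_mapping  5610    NA
#> 3:         paired  5228  2614
#> 4:   deduplicated  5228  2614
#> 5:     depth_le_5  5156  2578
#> 6:     assessment  5156  2578

res <- assess_assembly(cleaned$pairs, assembly$lengths, lib)
res$discrepancies[kind != "CONSISTENT",
                  .(scaffold, start, end, kind, support, median_span)]
#>     scaffold  start    end           kind support median_span
#>  1:  scf_001  93089 157553       DELETION      13     23161.0
#>  2:  scf_001 357363 442823      INSERTION      22     53968.0
#>  3:  scf_001 650208 740750      INSERTION      19     53067.0
#>  4:  scf_001 826866 864311        NEWJOIN      19          NA
#>  ...
#>  7:  scf_002 363714 424721       DELETION      19     22322.5
#>  8:  scf_002 628946 762109 MISORIENTATION      19     48554.0
```

Reading the calls: a `DELETION` window's pairs span only ~23 kb where
~38 kb were expected — the assembly is missing ~15 kb there (the truth
table confirms a 15-kb deletion at 120 kb). The `MISORIENTATION` windows
bracket the injected 50-kb inversion; the `NEWJOIN` windows flank the
chimeric tail swap, pointing at the scaffold that carries the displaced
sequence.

Scaffolding a fragmented (error-free) version of the same genome:

```r
contigs <- inject_errors(genome, fragments = fixture_fragments(genome$length, 20,
                                                               seed = 1))
sim2 <- simulate_matepairs(genome, contigs, lib, seed = 3)
cl2  <- clean_placements(sim2$placements, profile = "scaffolding",
                         lengths = contigs$lengths)
sc   <- scaffold_assembly(cl2$pairs, contigs$records, lib)
adjacency_eval(sc$paths, contigs$adjacency)[c("n_recovered", "n_true", "n_wrong")]
#> $n_recovered [1] 19   $n_true [1] 19   $n_wrong [1] 0
rbind(cbind(stage = "before", sc$stats_before), cbind(stage = "after", sc$stats_after))
#>     stage n_sequences total_bp largest     n50     n10
#> 1: before          20  2000000  127869  104799  120419
#> 2:  after           1  2001384 2001384 2001384 2001384
```

All 19 true neighbour relationships are rebuilt, none wrongly, and the 20
contigs collapse into one scaffold (`sc$records` is the FASTA;
`write_agp(sc$paths, ...)` emits the AGP).

A thin command-line wrapper over the same functions ships in
`inst/cli/matelink.R` (subcommands `simulate`, `clean`, `assess`,
`scaffold`, `stats`, `sweep`; see `--help`).

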