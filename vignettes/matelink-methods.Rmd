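---
title: "matelink: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{matelink: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`matelink` assesses and improves genome assemblies with long-insert
(fosmid-scale) mate-pair jumping libraries. This vignette records the model
the package implements, the semantics of every tunable parameter, what the
synthetic benchmark does and does not emulate, and the design decisions
taken where more than one reasonable choice existed. It states no empirical
result beyond what the package's own tests and `scripts/acceptance.R`
compute.

## The measurement model

A jumping library clones ~38-kb fragments and sequences both ends, so each
mapped pair reports a genomic distance and a relative orientation. We model
the insert — always the **outer distance**, `max(end1, end2) − min(start1,
start2)`, the quantity the library's size selection actually controls — as
Normal:

* `mu` (default **37,725 bp**) and `sigma` (default **4,200 bp**) define a
  `library_model`. `sigma` is a genuine library property: whenever
  alignments to a large reference are available,
  `estimate_insert_distribution()` should replace the default. The default
  is chosen so that `mu ± 3·sigma` reproduces the conventional ~25-kb /
  ~50-kb working band for a ~38-kb library (`(50,000 − 37,725)/3 ≈
  (37,725 − 25,000)/3 ≈ 4,200`).
* The **consistency band** is `mu ± 3·sigma`. Three standard deviations is
  the natural operating point: tighter bands flag ordinary sampling
  variation, wider bands hide real flaws. It also sets the **sensitivity
  floor**: an insertion or deletion smaller than ~`3·sigma` (≈ 12.6 kb at
  the defaults) shifts spans by less than the band half-width and cannot be
  called reliably. This floor is a property of the library, not a
  parameter.

Read geometry is configurable (`geometry = "outward"` by default, the
orientation produced by circularisation-based jump protocols; `"inward"`
for FR libraries). A same-scaffold pair is `expected` when its strands
match the geometry, `reversed` when both reads share a strand (the
inversion signal), `tandem` otherwise.

## Read cleaning

Filters run in a fixed order, each idempotent, with per-stage counts
logged:

1. **multi-mappers** (`n_hits > 1`) are dropped — a repeat-derived read
   carries no usable long-range information;
2. pairs are formed; **orphans** (mate unmapped) drop out;
3. **positional duplicates** — identical (scaffold, outer coordinates,
   strand) on both sides — collapse to the lexicographically smallest pair
   id, the standard duplicate-marking criterion;
4. the **repeat-depth screen**: exact per-base depth is computed from the
   placements (reads only, not spanned inserts) and every placement
   overlapping a maximal interval of depth > `depth_max` (default **5**) is
   removed with its mate. Genome-wide repeats of insert scale pile
   mate-pairs into deep stacks that survive the multi-mapper filter when
   one end is unique; the depth screen removes them;
5. the **profile filter**: `scaffolding` additionally drops wrongly
   oriented pairs (joins need clean constraints); `assessment` keeps them —
   they are the mis-orientation signal.

Insert estimation uses same-scaffold, expected-orientation pairs with spans
in a **fit window** (default 10–80 kb). The window keeps chimeric
ultra-long spans and short-range artefacts from corrupting the moments of a
unimodal ~38-kb distribution; at least 100 qualifying pairs are required,
and a degenerate (zero-variance) sample is an error rather than a
zero-width band.

## The driver/follower window scan

Every pair contributes two directed read-sides (read → mate). Within a
(scaffold, mate-scaffold) group, a **window** is a *maximal* set of sides
such that read starts span less than `driver_max` (**10 kb**), mate starts
span less than `follower_max` (**20 kb**), and at least `min_support`
(**5**) distinct pairs participate. Maximality is the precise version of
"sliding": every maximal set is induced by an anchor pair (its smallest
read start, its smallest mate start), so the scan enumerates anchors,
prunes follower runs that gain no member, and removes dominated sets with a
bounding-box test (a set is contained in another exactly when its bounding
box fits inside the other's generating rectangle). The test suite checks
this scan against a brute-force enumeration of all anchor rectangles with
explicit subset filtering on hundreds of random instances.

Support counts **distinct pairs**, not sides: a short-span pair can place
both of its reads inside one driver window and must not count twice.

Sides supporting no window are re-clustered per scaffold; a run of at least
`min_support` window-less pairs within `driver_max` becomes
*follower-absent* evidence — the raw material for mis-join calls.

### Classification

Each window receives exactly one call, in a fixed decision order: follower
on another scaffold → `NEWJOIN`; follower absent → `BREAK`; reversed
orientation consensus (majority of pairs) → `MISORIENTATION`; median span
above / below the band → `INSERTION` / `DELETION`; otherwise `CONSISTENT`.
The order is a design choice (location evidence before orientation before
size): a window whose mates sit on another scaffold has no meaningful span,
and a reversed window's span is distorted by the inversion itself. The
median span (not the mean) is classified, for robustness to a single
aberrant pair. Boundary values are not calls: strict inequalities, so a
median exactly at `mu ± 3·sigma` stays consistent.

`BREAK` calls pass two guards:

* **end exemption** — drivers within `mu + 3·sigma` of a scaffold end are
  exempt, their mates legitimately fall off the sequence;
* **consistency guard** — a follower-absent run whose driver interval
  overlaps a `CONSISTENT` window is suppressed. A locus tiled by correctly
  spanning pairs is explained; the stragglers there are sampling noise, and
  without this guard chance co-location of window-less sides would
  occasionally fabricate breaks on flawless assemblies.

Overlapping calls of the same class merge into maximal intervals (support =
maximum, span = median of medians). A caveat on reported intervals: a
same-scaffold discrepancy is reported as the full driver-to-follower
extent, so a *compound* flaw (e.g. a fragment boundary interacting with a
chimeric tail swap) can yield a very long `INSERTION` interval whose span
is far beyond the band; the call is correct — the two loci do not belong at
that distance — but the interval should be read as "discordance across this
range", not as a 900-kb inserted segment.

### Consistency summary

Per scaffold: `assessable` (length ≥ `mu + 3·sigma` — anything shorter
cannot hold a full insert), `fully_consistent` (≥ 1 window and zero
non-consistent calls), and the bases under the union of consistent window
extents. Assembly-level fractions are reported against **both**
denominators (all scaffolds and assessable-only), since which denominator
is appropriate depends on whether short scaffolds are considered part of
the assembly under assessment. Coverage evenness is summarised by counting
pairs per fixed-width bin (default **100 kb**) along each scaffold.

## Scaffolding

Cross-scaffold pairs vote for joins between scaffold ends. A read implies
the end its mate points at (outward geometry: a `−` read points right, i.e.
tail); reads farther than `mu + 3·sigma` from that end are discarded — the
mate could not reach another scaffold. Candidates need `min_support`
(default **5**) pairs; the gap is the median of `mu − d_a − d_b` with `d`
the read-to-end distances.

The **ambiguity guard**: an end with several candidates keeps the strongest
only if its support is at least `dominance` (default **2**) times the
runner-up's; otherwise *all* candidates at that end are dropped. The guard
deliberately trades recall for precision — in this evidence regime a wrong
join is far more damaging than a missed one, and the benchmark requires
zero wrong-neighbour/wrong-strand joins. Surviving edges give every end
degree ≤ 1; residual cycles (possible with circular or repetitive
structures) are broken at their weakest edge, leaving a union of simple
paths.

Linearization walks each path from a free end, propagating orientation
(enter through the head → `+`). Output is canonical: each path is reported
in the direction that puts its lexicographically smallest contig on `+`,
paths are ordered by first contig, so results are invariant to input
permutation. Gap estimates below `min_gap` (default **20 bp**, the
conventional minimal scaffold gap) are clamped — negative estimates mean
slight overlap, whose resolution is out of scope — and rounded to whole
bases so FASTA `N`-runs and AGP gap rows agree exactly. Joins never modify
the interior of existing scaffolds; breaking at `BREAK` calls before
re-scaffolding is a separate, explicit step the user may take.

N50 (N10) is the length at which the descending cumulative length first
reaches 50% (10%) of the total.

## The simulator

The simulator exists to close the loop: known flaws in, classified calls
out. Its pieces:

* `sim_genome()` — uniform background at a target GC (default 0.46) with
  repeat families (default 5 families × 20 copies × 5 kb on the 10-Mb
  fixture) placed non-overlapping, each copy mutated at 2% of positions
  (≥ 95% within-family identity). Repeats are what make multi-mapping and
  deep stacks happen, so the cleaning filters are exercised, not bypassed.
* `inject_errors()` — fragmentation (recording true adjacencies) plus
  deletions, in-place duplications ("insertions" from the assembly's
  viewpoint), inversions, and chimeric tail swaps, maintained as a block
  map from assembly coordinates to genome source intervals.
* `simulate_matepairs()` — pairs drawn on the *true* genome (insert
  truncated below at `2·read_len`, so overlapping-read pairs never arise —
  mirroring their removal in real pipelines) and projected through the
  block map. Reads in deleted sequence vanish (orphans), reads in
  duplicated sequence get `n_hits = 2`, reads in inverted blocks flip
  strand, reads inside repeat copies receive the family copy number as
  `n_hits`, and a configurable fraction of pairs is emitted twice as
  duplicates. Pairs spanning a flaw therefore produce exactly the
  discordant signal the assessment engine is built to detect.

What the simulator does **not** emulate: sequencing errors and base
qualities, alignment ambiguity beyond the `n_hits` bookkeeping, chimeric
library artefacts, PCR bias along the genome, and gap-containing input
scaffolds. Reads are idealized placements — perfect mapping at the true
location. Passing benchmarks therefore demonstrate the *method's*
correctness given faithful alignments; they do not certify behaviour under
aligner-specific failure modes, which enter real analyses upstream of this
package.

A chimeric tail swap leaves the displaced sequence elsewhere in the
assembly, so its junction announces itself as `NEWJOIN` evidence (mates
cluster on the partner scaffold) rather than as mate-less `BREAK`; a
`BREAK` appears when the true counterpart is missing altogether. The
benchmark accordingly accepts either call at a chimeric junction, and
localization is scored to within one `mu + 3·sigma` — a mate-pair method
cannot place a breakpoint more precisely than its insert spread.

### Benchmark conditions and problem sizes

The standard fixture is a **10-Mb genome, seed 42**, with mate pairs at the
library design point: 250-bp reads, **0.75×** sequence coverage (15,000
pairs; ~56× physical coverage). Error layouts place 20 deletions (15 kb),
20 insertions (15 kb), 10 inversions (50 kb) and 10 chimeric junctions on
10 equal scaffolds, slots ≥ 50 kb apart and ≥ 100 kb from scaffold ends so
individual flaws are resolvable; the scaffolding fixture cuts the genome
into 100 contigs of jittered size (each ≥ 60% of the 100-kb mean, hence
longer than the library's upper span). The coverage sweep uses a 3-Mb
genome with proportionally fewer errors and 30 contigs, two replicates per
grid point — sizes chosen to keep the whole benchmark suite in the
low tens of seconds while leaving every rate estimated from dozens of
events. The monotonicity check on the sweep allows a 1-percentage-point
slack between consecutive coverages, fixed in advance as the Monte Carlo
jitter of two-replicate rate estimates at saturation.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally; 1-based only at
  format boundaries (SAM in, AGP out). All coordinates are whole numbers.
* Ties in the scan are broken deterministically (sort by scaffold, start,
  mate scaffold, mate start, pair id); equal-support join candidates at one
  end are ordered by insertion, and the dominance test uses the top two.
* `sigma = 0` (all spans identical) is an error, not an epsilon.
* Empty inputs return empty, well-typed tables; writers emit headers.
* An assembly with no joinable evidence scaffolds into singleton paths
  unchanged (N50 unchanged, conservation exact).

## Known limitations

* Flaws smaller than ~`3·sigma` are below the sensitivity floor by design.
* The outermost `mu + 3·sigma` of every scaffold is blind for `BREAK`
  calls (end exemption) and thin for everything else; short scaffolds
  (< `upper`) are not assessable at all.
* Breakpoints are localized to window resolution, not base pair.
* Compound flaws closer than one insert length merge into composite calls.
* The scaffolder emits paths only; it will not resolve genuine branching
  (e.g. haplotype duplication) and discards such evidence by design.
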