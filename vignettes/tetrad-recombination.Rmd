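---
title: "Tetrad-based recombination analysis with tetrarec: models, parameters and design choices"
author: "tetrarec authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tetrad-based recombination analysis with tetrarec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrarec)
library(data.table)
```

## The biological model

A tetrad is the set of four gamete cells (labeled a, b, c, d) produced by a
single meiosis. At any genomic position, the four chromatids carry two
copies of each parental haplotype, so a biallelic marker that distinguishes
the two crossing parents (P1, P2) segregates 2:2 across the tetrad — except
locally, where recombination intervened:

* a **crossover (CO)** is a reciprocal exchange of chromosome arms between
  one P1-origin and one P2-origin chromatid: downstream of the breakpoint
  the two chromatids swap haplotypes, preserving 2:2 segregation but
  changing *which* gametes carry which parent;
* a **non-crossover (NCO)** leaves the arms intact but converts one
  chromatid to the other parent's alleles inside a **gene-conversion (GC)
  tract**, producing local 3:1 (or 1:3) segregation;
* every CO also carries a GC tract at its breakpoint. Whether that tract is
  *seen* depends entirely on whether a marker happens to fall inside it,
  which motivates the field's four observable event types: CO without
  detectable tract (Type 1 CO), CO with detectable tract (Type 2 CO), the
  tract of a Type 2 CO (Type 2 GC), and the NCO tract (Type 1 GC). Type 1
  and Type 2 COs are biologically the same event.

tetrarec reconstructs these events from per-gamete sequencing evidence in
three stages — marker cataloguing, gamete genotyping, and linkage-block
profiling — and ships a tetrad simulator that generates all of the above
with known ground truth.

## Marker catalog

Markers are homozygous biallelic SNVs segregating between the parents.
Because ambiguous markers are the dominant failure mode of downstream event
calling, candidates are filtered aggressively:

* inside repeat or CNV intervals (BED input) — removed;
* within 10 bp of an indel anchor position (`indel_flank_bp`, interpreted
  as `|marker - indel POS| <= 10`; the indel's span is not expanded, since
  only the anchor is well-defined across callers) — removed;
* per-site depth strictly above 1.5x or strictly below 0.5x the
  chromosome-wide median depth (computed over *all* positions of the depth
  table, zeros included) — removed. The inequalities are strict, so
  boundary sites are retained.

For parent-based analysis, two directional call sets are reduced to their
reciprocal intersection (identical allele pair at coordinate-map-linked
positions), and a consensus catalog additionally requires support from the
genome-alignment set and both cross-parent mapping sets. The result is
symmetric with respect to the parents by construction. Filters commute, and
every candidate ends up either in the catalog or in the filter log with the
first reason that removed it.

## Genotyping model

Per (gamete, marker) cell the evidence is a vector of read counts and
summed Phred base qualities for A/C/G/T (from the simulator, a TSV, or the
`parse_mpileup()` adapter). Two scores gate the call:

* **Q_net** = qualsum(major base) − Σ qualsum(all other bases), the
  cumulative quality margin of the best-supported base (default cutoff 50);
* **base purity** = count(major) / total count (default cutoff 0.9).

The major base is defined by qualsum; an exact tie yields no call
(status `admixed`). A call is made only when the major base equals one of
the two parental alleles and both scores meet their cutoffs; every failure
mode is a status (`no_data`, `low_qnet`, `low_purity`, `admixed`,
`conflict`, `cnv_masked`). Q_net scales with depth, so lenient cutoffs
(10–20) are the right choice for shallow (~1X) data: the markers gained far
outnumber the extra errors, which the purity and biparental filters keep
rare. Sites with admixed signals can be reported separately as candidate
post-meiotic segregation (PMS) sites. Gamete-specific CNV regions are
masked to NA. In parent-based mode the two per-parent genotype matrices are
cross-validated: only *conflicting* calls are voided; a call present in one
space only is kept.

**Missing-genotype inference.** Genome-wide, segregation is 2:2 except in
GC tracts, whose cumulative footprint is small. NA cells are therefore
filled only when that ratio forces them uniquely: one NA against called
(2,1) or (1,2), or two NAs against (2,0)/(0,2). Observed (3,0)/(0,3)
patterns are *never* completed — they may be genuine 3:1 conversion sites.
Raw and inferred matrices are both kept: inference is what rescues a
3-viable-gamete tetrad (the dead gamete's genotypes follow from the other
three wherever all three are called), but inside GC tracts the 2:2
assumption is wrong by definition, so event profiling defaults to the raw
matrix (a forced fill at a 3:1 site whose fourth cell is uncovered would
fabricate a 2:2 marker inside a tract and split its linkage signal).

## Linkage blocks and event classification

Markers where all four gametes are called are classified by their 4-gamete
pattern; maximal runs of consecutive markers with the *identical pattern*
(not merely the same ratio class — two adjacent 2:2 runs differing by a
reciprocal switch are precisely a crossover) form preliminary blocks.
NA markers never split a block. Blocks below `min_markers` (default 1) or
`min_size_bp` (default 1) are dissolved — their markers ignored, flanking
same-pattern blocks merged — and final outer bounds are the midpoints
between a block's outermost markers and the nearest informative markers of
its neighbors, extended to position 1 and the chromosome end at the
extremes, so final blocks tile each chromosome exactly.

Adjacent-block transitions then classify as:

| observation | call |
|---|---|
| 2:2 → 2:2, reciprocal 2-gamete switch | CO_T1 at the boundary midpoint |
| 3:1 block, identical 2:2 flanks, one gamete out-and-back | GC_T1 on that gamete |
| 3:1 block, flanks differing by a reciprocal pair, middle deviating from each flank by one of the pair | CO_T2 + linked GC_T2 |
| terminal 3:1 block, single flank differing by one gamete | GC_T1 truncated at the chromosome end |
| 4:0/0:4 blocks, ≥3-gamete switches, any other chain | COMPLEX, with its pattern context, never dropped |

Two identities make the middle-block rule exact: a reciprocal switch of a
2:2 pattern flips both involved gametes, and a tract abutting the
breakpoint therefore differs from *each* flank by exactly one of the two
recombining gametes. The same identity means the tract carrier of a Type 2
GC is not identifiable from genotypes alone (tract-left on one chromatid
and tract-right on the other are observationally identical), so GC_T2
events are attributed to both recombining gametes, and truth comparison
uses the same convention.

Events within `merging_range_bp` on the same chromosome sharing a gamete
can be merged (type escalating to COMPLEX when they differ); the default is
0 — no merging — matching the package's reference analyses.

## The simulator and what it does (not) emulate

`simulate_tetrad()` draws events on a four-chromatid model: gametes a, b
start as P1, c, d as P2. Each CO picks one current P1-carrier and one
P2-carrier at its breakpoint and swaps them downstream; its Type 2 tract
(Normal(2500, 2000) bp truncated to [100, 5000], rejection-sampled)
abuts the breakpoint on a uniformly chosen side and chromatid of the
recombining pair; each NCO converts a uniformly chosen chromatid within a
Type 1 tract (Normal(2250, 2200), same truncation). These size parameters
are estimates from real budding yeast tetrads and are the package
defaults, as are 90 COs + 65 NCOs per meiosis and the yeast R64
chromosome lengths (~12.07 Mb) with ~50,000 uniformly placed markers
(mean spacing ~241 bp) for yeast-scale runs. Chromosomes are chosen
proportional to length and positions uniformly.

Placements are rejected (up to 1000 retries) unless every pair of event
footprints on a chromosome is disjoint *and* separated by at least one
catalog marker. The separation requirement goes slightly beyond plain
non-overlap by design: two events with no informative marker between them
collapse into a single observable linkage signal, which would make
per-event detectability — and any statement like "all detectable events
are recovered" — ill-defined.

Observations are direct per-marker evidence rather than reads: counts are
Poisson(depth), each read reports the true allele with probability
1 − base_error (default 1e-3) or a uniform other base, and contributes a
constant Phred quality (default 30) to its base's qualsum. This emulates
coverage sparsity and miscalls but **not** mapping ambiguity, indel
artifacts, quality heterogeneity along reads, or correlated errors —
passing simulations therefore validate the genotyping/profiling logic, not
robustness to alignment pathology (which the marker filters address on
real data). `config$seed` makes everything reproducible; observation noise
uses a fixed offset of the seed so that event placement and evidence noise
are decoupled but jointly deterministic.

**Detectability.** A tract is detectable iff it contains a marker. A CO is
detectable iff at least one marker flanks its breakpoint on each side
*outside its own tract* — a tract-interior marker shows 3:1 and cannot
witness the reciprocal switch. A Type 2 GC additionally requires its CO to
be detectable: when the CO is invisible, the tract presents exactly as an
NCO and is expected (and matched) as GC_T1. `expected_events()` encodes
this degradation map, and `compare_to_truth()` matches called against
expected events on chromosome, type, involved gametes, and interval
overlap.

## Numerical choices and degenerate inputs

* Qualsum ties → no call; a dominant non-parental base → `conflict`,
  regardless of its scores.
* Depth medians use all depth-table rows (zeros included); an all-zero
  chromosome loses its markers with a warning.
* Block boundaries are real-valued midpoints (x.5 allowed); CO breakpoints
  are the midpoint of the two flanking informative markers, with the
  flanking interval reported alongside since the true breakpoint is only
  localized to it.
* Tract sizes are rejection-sampled and rounded, so truncation bounds are
  exact in bp; a truncation window capturing negligible mass errors out
  rather than looping.
* Empty catalogs, zero-event configs, chromosomes with fewer than two
  markers, and empty consensus intersections all return well-formed empty
  results (with warnings where surprising).

## Validation scale and known limitations

The packaged tests validate: exact event census (90/90/65 at the default
configuration); 100% recall and precision of detectable events at 8X
noise-free depth for Q_net cutoffs 10–100; recovery of a fully masked
gamete outside GC tracts at 4X; equivalence of the block-based classifier
with a brute-force transition-enumeration oracle on 500 random matrices;
determinism and Q_net monotonicity; and 1X error behaviour averaged over
five seeds (raw error ≈ 2e-4 with Q_net 10). Yeast-scale runs (200,000
cells) complete in seconds, so no test subsamples the study conditions.

One measured quantity deserves comment: after 2:2 inference at 1X the
inferred-genotype error is ≈ 4.5e-3, dominated not by sequencing error but
by forced fills at tract-interior 3:1 markers (≈ 3% of markers) whose
uncovered cell makes the 2:2 fill wrong with probability ≈ 0.44. This is a
structural property of the fill rule at Poisson-1X coverage: users wanting
a lower inferred error at shallow depth should profile the raw matrix (the
default) or restrict inference to single-NA patterns.

Beyond that: PMS sites are reported, not classified; the COMPLEX class
collapses the long tail of multi-chromatid patterns (double COs at a
point, 4:0 tracts) and reports the raw pattern context so users can
re-classify; mapping/variant calling and CNV discovery are out of scope —
their products (BAM-derived observation tables, CNV BEDs, SNV call sets)
are consumed as inputs.
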