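---
title: "Occupancy analysis with chipfold: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy analysis with chipfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipfold)
```

`chipfold` analyses how the genomic occupancy of a chromatin mark changes
between two growth conditions — the motivating case is a histone
phosphorylation responding to a shift from a fermentable to a
non-fermentable carbon source — and how those changes relate to gene
expression. This vignette is the package's own account of the models and
conventions behind each stage, the parameters that matter, and the design
choices taken where more than one reasonable convention exists.

## Coordinates and containers

All internal coordinates are **0-based half-open** (BED convention): the
interval `[start, end)` covers `end - start` bases. GTF input and output
(1-based inclusive) is converted at the boundary, so positional logic —
peak calling, merging, closest-TSS search — mirrors bedtools semantics
throughout. On the minus strand the TSS is the interval's *last* base
(`end - 1`); this is the standard convention and makes the plus/minus cases
symmetric.

Coverage is held as one dense numeric vector per chromosome
(`coverage_track`). Dense vectors rather than run-length encodings keep the
ratio, smoothing and interpolation code one-line simple; the synthetic
genomes used throughout are at most a few megabases, so memory is not a
concern. Peak sets are data frames with a validated invariant — sorted by
`(chrom, start)`, pairwise disjoint within a chromosome — that every
constructor enforces and every test exercises.

## The peak caller

A position is *enriched* when the per-base ratio

$$ r_i = \frac{\mathrm{IP}_i + \varepsilon}{\mathrm{input}_i + \varepsilon} $$

reaches the fold threshold; a raw peak is a maximal run of enriched
positions at least `min_run` bases long; raw peaks whose gap is strictly
below `merge_gap` are merged. The defaults (`fold_threshold = 2`,
`min_run = 50`, `merge_gap = 400`) are the published rule the package
reimplements. Four conventions are deliberately pinned down:

- **"Closer than 400 bases" is strict**: a gap of exactly 400 does not
  merge. This is the literal reading of "closer than"; the boundary is
  covered by tests on gaps of 399 and 400.
- **"Extending for 50 bases" is inclusive**: a run of exactly 50 qualifies.
- **The pseudocount** `ε` (default 1 signal unit) is added to numerator and
  denominator alike, so an empty position (0/0) has ratio exactly 1 and can
  never seed a peak, while well-covered positions are essentially
  unaffected.
- **Depth normalisation is on by default**: both tracks are scaled to the
  mean of their totals before the ratio, since a raw 2-fold cut is
  meaningless across unequal sequencing depths. The synthetic generator's
  `depth_ratio` parameter exists precisely to keep this stage testable.

The fold criterion is applied per base on the normalised ratio (not on
windows or smoothed tracks); whether the original analysis smoothed first
is not recoverable, so the simplest fully specified rule was fixed and the
exact-recovery tests are written against it. Merging is a single
left-to-right sweep, which provably reaches the fixed point of repeated
pairwise merging (a merged interval spans its members, so the next gap
tested is the same gap pairwise merging would see); an explicit
fixed-point oracle cross-checks this in the tests. Merged scores are
length-weighted means of member scores, weighting by member lengths rather
than the merged span so that the gap contributes nothing.

One consequence of total-signal normalisation worth knowing: planted
enrichment adds to the IP total, so after normalisation the background
ratio sits slightly below 1 and in-peak ratios slightly below the planted
fold (by the factor `G / (G + Σ(fold-1)·len)`, under 1% in all shipped
conditions). The exact-recovery guarantee is unaffected because the ratio
is piecewise constant.

## Differential occupancy

The differential stage is a documented, fully specified stand-in for
affinity-model tools (the published analysis delegated this step to a
package whose settings are not stated, so its 366-up/139-down counts are
not a reproduction target). Consensus regions are the union-merge of both
conditions' peaks (overlapping or adjacent intervals always coalesce).
Each region gets per-million-scaled summed IP signal per condition and

$$ \log_2\!\mathrm{FC} = \log_2\frac{s_B + 1}{s_A + 1}, $$

labelled `up`/`down` at `|log2FC| ≥ 1` (two-fold). The pseudocount of 1 on
per-million values makes the statistic antisymmetric under swapping
conditions — a property the tests check exactly. The optional Fisher gate
builds a 2×2 table of rounded region counts against the library remainder;
it is approximate (scaled sums are not integer counts) and off by default.

## Gene assignment

Peaks are assigned to the gene whose TSS minimises the interval distance:
0 when the TSS lies inside the peak, otherwise the distance to the nearer
peak boundary. Distance is strand-agnostic and measured from the interval,
not the midpoint, matching bedtools `closest`. Ties are broken by the
lexicographically smallest gene id and flagged, which keeps assignments
deterministic. Pol III, tRNA and rRNA genes are removed **before** the
search, so a filtered gene cannot absorb a peak that would otherwise
report its protein-coding neighbour; this is the stricter of the two
readings of filter-then-report and is applied consistently. A vectorised
search is cross-checked against an exhaustive double loop on a thousand
random instances.

## Enrichment statistics

Term enrichment is the upper-tail hypergeometric test
`P(X ≥ k)` via `phyper`, with fold enrichment `(k/n)/(K/N)` — the term's
frequency in the significant list over its frequency in the universe — and
results ordered by fold enrichment. Inclusion follows the published rule:
raw `p < 0.05` and at least two annotated list genes. Raw p-values are the
default because the figure being mirrored showed raw-p terms;
Benjamini–Hochberg is exposed behind `adjust = TRUE` as the safer option.
The universe defaults to the filtered Pol II gene set (the same set the
assignments draw from); it is configurable because the original choice of
universe is not stated. The test suite pins the tail probability against
literal enumeration of all draws for small universes and against the
support-sum formula for every configuration up to `N = 25`.

## Metagene profiles

Per-gene vectors are taken either TSS-anchored (±2000 bases, 5'→3') or
transcript-scaled (±500-base flanks at base resolution, body linearly
interpolated onto a fixed grid via `approx`). The body grid is 1000 points;
no published bin count exists, and 1000 is fine enough that a body of
typical gene length resamples with sub-base error while keeping profile
matrices small. Each gene's vector is smoothed with a centred 101-base
moving average whose window shrinks at the edges (output length equals
input length), then genes are averaged positionwise, ignoring missing
values and recording the per-position gene count. Smoothing gene-first
versus averaging-first commute on complete data; gene-first is fixed so
that missing stretches at chromosome ends are smoothed within, never
across, genes.

## Expression analyses

RPKM is `count / (length_kb × library_millions)`. Quantile groups sort
ascending by value — ties broken by gene id, so the partition is
deterministic — and split into contiguous groups whose sizes differ by at
most one, the first `n mod k` groups taking the extra gene; 6,775 genes in
five groups therefore give exactly 1,355 per group.

The differential-expression test is an exact conditional binomial on
pooled counts with library-size offsets: for each gene with pooled counts
`a`, `b` and pooled library sizes `L_A`, `L_B`, the two-sided test of
`b ~ Binomial(a + b, L_B/(L_A + L_B))`. A gene is called DE at BH-adjusted
`p < 0.05` and two-fold change (pseudocount 1 on per-million values). This
has the same decision-rule shape as count-model packages while being fully
specified in a few lines; it does **not** model biological overdispersion,
so it is calibrated only for the shipped `dispersion = 0` conditions — a
deliberate scope limit, since negative-binomial GLM internals are not this
package's contribution. A second known limitation is shared with all
total-count normalisation: strongly asymmetric planting shifts the library
totals, which can push null genes' fold changes toward the threshold. The
null simulations (symmetric) show type-I control at `alpha`; the power
fixture plants one-sided effects and asserts planted-gene recovery, not
exclusivity.

The dependence scatter takes per-gene `x = log2((gly_wt+1)/(glu_wt+1))`
and `y = log2((gly_mut+1)/(gly_wt+1))` on per-million values. A mutant that
exactly reverts the condition response gives `y = -x` and Pearson `r = -1`
to machine precision; zero-variance degenerate inputs report `r` as
missing with a warning rather than erroring, because an exactly reverting
or exactly inert mutant is a legitimate edge case of the construction.

## The synthetic generator and what passing tests mean

The generator plants known truth at every level: enriched intervals with
stated folds over a flat background (input mean `background_level`
everywhere; IP mean multiplied by the fold inside regions, then globally
scaled by `depth_ratio`), negative-binomial counts with variance
`m + φm²` (`φ = 0` is Poisson), and a term map containing one term whose
membership is reproduced exactly. Default conditions — one 500 kb
chromosome, 100 genes (10% non-Pol II), background 50, planted fold 3,
fold-3 regions ≈500 bases, 3 samples per group at baseline mean 200 —
were chosen once as representative of a compact yeast-scale experiment and
keep the full suite and pipelines inside seconds on one CPU.

What the generator does *not* emulate bounds what green tests can claim:
no read-level artefacts (mappability, GC bias, fragment-length effects),
no spatially structured background, no biological replicate variability
beyond the count noise model, and coverage is taken as given rather than
built from reads (whether reads were extended or shifted upstream of
coverage is not modelled). Passing tests therefore demonstrate the
correctness of the computations and conventions, not robustness to every
artefact of real sequencing data.

## Numerical choices and degenerate inputs

- Ratios are guarded by the pseudocount; depth normalisation refuses
  zero-total tracks.
- `phyper`/`p.adjust`/`cor`/`binom.test`/`fisher.test`/`approx` supply the
  standard numerics; the package's own tests pin each against independent
  oracles (enumeration, step-up formula, closed forms) rather than trusting
  them blindly.
- Empty peak sets, empty gene lists, all-filtered gene tables, zero-count
  genes and missing-strand records all have defined behaviour (empty
  results or warnings, never silent wrong answers); errors name the
  offending file, line or gene where they can.
- Every randomised stage takes an explicit seed; the pipelines derive
  per-stage seeds from one top-level seed by fixed offsets and record them
  in the run log, so full runs are byte-identical for a fixed seed.

## Problem sizes

The shipped test and acceptance conditions use: 100–200 kb single-chromosome
genomes for caller tests, 20 Poisson replicates of five fold-3 regions for
stochastic recovery, 1,000 random peaks × 100 genes for the closest-TSS
oracle, every hypergeometric configuration up to `N = 25`, 1,000 random
p-vectors for the BH check, a 1,000-gene null simulation for DE
calibration, and the full two-workflow pipeline at the default 500 kb / 100
gene conditions. These sizes make every property checkable in seconds while
leaving each statistic enough resolution to fail visibly if a convention
regresses.
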