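---
title: "Inferring microRNA activity from target repression footprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring microRNA activity from target repression footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miractivity)
```

## The model

MicroRNAs repress their targets. `miractivity` therefore treats "activity of
miRNA *m* in cell *s*" as a statement about the *joint position of m's
target genes* in the expression profile of *s*: if *m* is active, its
targets should crowd the low end. Three assumptions make this testable:

1. **A trustworthy target catalogue.** Only experimentally supported
   miRNA–target interactions are used, filtered to functional pairs backed
   by at least one strong evidence or two weak ones (evidence rows are
   pooled per pair before the rule is applied, since catalogues store one
   row per supporting reference). Weaker, purely predicted interactions
   would dilute the binary membership vector and with it the test's power.
2. **Cross-sample standardisation carries the signal.** Raw counts say
   little about repression; what matters is a gene sitting *low relative to
   its own behaviour across cells*. After scaling every cell/spot to a
   common total (10,000 by default), each gene is z-scored across the `S`
   samples with the population denominator (`1/S`), matching the definition
   of the statistic being tested rather than an unbiased variance estimate.
   Genes with zero variance carry no ranking information and are dropped.
3. **Rank evidence, not magnitude evidence.** The test consumes only the
   ascending-z ranking of genes within a cell, so it is invariant to any
   monotone distortion of the normalised expression scale.

### The mHG test

For the binary membership list λ of length `N` with `K` ones, the statistic
is the minimum over prefix cutoffs of the hypergeometric upper tail,
`min_n P(X ≥ b_n)` with `X ~ Hypergeometric(N, K, n)`. Because the cutoff is
optimised, the statistic is an optimistically biased tail probability; the
exact correction counts, among all `C(N, K)` arrangements of the ones, the
fraction whose statistic is at least as extreme. `mhg_pvalue_dp()` performs
this count with a dynamic program over the `(n, b)` lattice:

* lattice cells whose tail probability is ≤ the observed statistic form the
  rejection region; since the tail decreases in `b` and increases in `n`,
  the region's lower boundary `r(n)` is nondecreasing and is found with a
  single two-pointer sweep (amortised `N + K` tail evaluations);
* live path counts (arrangements avoiding the region) are advanced row by
  row; mass that first enters the region at `(n, r(n))` is multiplied by its
  `C(N−n, K−r(n))` completions and accumulated directly as a probability.

Accumulating the *absorbed* mass rather than `1 − (surviving mass)` avoids
catastrophic cancellation for small p-values; path counts are kept in
scaled floating point (power-of-ten shifts) so `N` in the tens of thousands
does not overflow; each absorbed term is normalised in log space. Boundary
membership uses a relative tolerance of 1e−12 so that tails computed along
different code paths compare as equal; the returned p-value is clamped to
`≥ statistic` (the observed event at the minimising cutoff alone implies
the rejection event, and the clamp removes ~2-ulp log-space round-off).
`mhg_pvalue_bruteforce()` is a literal enumeration of the definition and
serves as the independent oracle: the suite checks DP–oracle agreement for
*every* binary list up to `N = 10` at 1e−10 relative tolerance.

The implementation also accepts optional cutoff bounds `(X, L)` (minimum
ones in the prefix, maximum cutoff), defaulting to `(1, N)` — the plain
test over the full range, which is what every pipeline entry point uses.

### Degenerate inputs and tie-breaks

* `K = 0` (no target present in the matrix): the p-value is exactly 1, by
  construction in the DP and short-circuited in the activity matrix.
* Ties in z within a cell are broken by ascending gene identifier. This
  makes results reproducible and independent of matrix row order (checked
  bitwise in the tests), at the price of a documented convention
  dependence; expression ties in the agreement analyses are broken the
  same way.
* All-tied rank-sum comparisons have zero rank variance and return p = 1
  rather than dividing by zero.
* Ties among equal minimising tails report the smallest cutoff `n*`
  (reporting only; the p-value is unaffected).

## Aggregation modes and their parameters

| parameter | default | meaning |
|---|---|---|
| normalisation total | 10,000 counts/cell | common depth before z-scoring |
| cell subsample | 10,000 cells | tractability cap, uniform without replacement (stratified per population in comparative mode), fixed default seed |
| low-count filter | off (1,000 reads when enabled) | opt-in guard against cells whose sparse profiles distort z-scores |
| spatial activity threshold | p < 1e−5 (strict) | a spot counts as "active" for the spatial score |
| comparative population size | warn below 100 cells | rank-sum normal approximation and score stability |
| tier quantiles / score ceiling | 0.97, 0.9 / 1e−8 | comparative ranking tiers |
| classification thresholds | active < 0.05, non-active > 0.1 | expression-agreement analyses |

**Total mode** averages activity p-values per miRNA and applies
Benjamini–Hochberg across miRNAs. The mean of per-cell p-values is a
heuristic aggregate, not itself a p-value; a conservative p-value merging
rule could be substituted where calibrated totals are needed, but the mean
is the default because it is the scale on which the downstream
classification thresholds are defined.

**Comparative mode** compares the two populations' activity p-values per
miRNA with a two-sided Wilcoxon rank-sum test — midranks, tie-corrected
variance, no continuity correction (the mode targets populations of ≥ 100
cells where the approximation is excellent) — then BH across miRNAs.

**Tiering.** The ranking promotes miRNAs that are differentially *and*
consistently active. "Consistently high activity" is measured as the
per-population mean of −log10 p per miRNA, compared against the 0.97 (tier
1) and 0.9 (tier 2) empirical quantiles of that quantity across miRNAs
(linear-interpolation estimator), combined with a BH score below 1e−8.
The −log10 scale is a genuine design choice: a quantile rule on raw mean
p-values would select the *least* active miRNAs, which contradicts the
rule's purpose, so the activity scale (where larger = more active) is
used; the quantile probabilities are exposed as arguments for users who
want the other reading.

## The synthetic-data module

Every test and example runs on data from `generate_single_cell_dataset()` /
`generate_spatial_dataset()`: negative-binomial counts with log-normal
means across genes (`meanlog = log 20`, `sdlog = 0.8`, dispersion
`size = 10`), i.e. a few hundred moderately expressed genes with realistic
overdispersion — the regime in which a δ = 2 standard-deviation shift is
actually representable. Activity is planted *on the means*, not on the
z-scores: target means are multiplied by `max(0, 1 − δ·cv)` (cv the NB
coefficient of variation), which shifts the post-pipeline z-score of a
target by approximately −δ, saturating at complete silencing for genes too
noisy to absorb the full shift. Planting upstream of normalisation means
the tests exercise the whole pipeline, including the compositional side
effect that knocking down targets slightly inflates every other gene after
depth renormalisation — visible as weak, expression-corroborated
runner-up scores in the worked example.

Default study conditions, used throughout the tests: δ = 2, 20 targets per
miRNA, 200 cells per population, a 500-gene universe, 10 miRNAs. Two
scenario variants are worth noting:

* `generate_mti_fixture(disjoint = TRUE)` draws mutually disjoint target
  sets. Real catalogues overlap (the package ships `target_jaccard()`
  precisely because they do), but for attribution tests — "is every
  differential-activity hit corroborated at the expression level?" — shared
  targets make secondary miRNAs genuinely partially active and confound
  the question, so that test isolates per-miRNA signal with disjoint sets.
* The **universal activity** scenario plants *different target subsets in
  different cell subsets* (10 subsets of 20 targets from a 200-target
  catalogue in a 2,000-gene universe, δ = 3, i.e. strong repression): the
  miRNA is active in every cell, yet no single target is repressed in more
  than 10% of cells. This is the adversarial case for cross-cell
  z-scoring — each target's own baseline is contaminated by its repressed
  cells — and the regression test requires activity p < 0.01 in ≥ 95% of
  cells. The scenario needs the larger universe because the per-cell
  evidence is `per-subset` targets deep, competing against the noise tail
  of all other genes.

What passing these tests does *not* show: robustness to batch effects,
ambient RNA, doublets, cell-type compositional structure, or annotation
error in real target catalogues — the generator models none of these. The
synthetic baseline is also unimodal per gene; real data's zero inflation
and multimodality will loosen the mapping between δ and the realised
z-shift, though the rank-based test only needs the ordering to survive.

## Problem sizes and determinism

The shipped test-suite and acceptance checks run at deliberately desk-sized
conditions — DP lattices up to 1462 × 740, exhaustive oracle enumeration to
N = 10, 20-seed recovery and 50-seed calibration loops at 200–400 cells —
sizes at which the exact statistics are still independently checkable by
enumeration and closed forms. All simulation entry points take explicit
seeds and restore the RNG state (`withr::with_seed`), the activity matrix
is reproducible bitwise under gene- and cell-order permutation and under
any worker count, and the default subsampling seed is fixed so repeated
pipeline runs are identical.

## Known limitations

* Gene symbols are matched after uppercasing, with no alias resolution; a
  catalogue/matrix vocabulary mismatch silently shrinks `K` (an absent
  target set returns p = 1 rather than an error, by design).
* Activity p-values are conservative for null miRNAs (checked as
  super-uniformity in the tests), so calibrated type-I control holds, but
  mean-p aggregates in total mode inherit the conservatism.
* The comparative rank-sum detects *any* distributional difference in
  activity p-values, including the depth-renormalisation echo of a strong
  signal elsewhere; tiering and expression-level corroboration
  (`compare_target_expression()`) are the intended guards.
* The 2-D embedding used for single-cell activity maps is delegated to
  uwot's UMAP and treated as opaque; only its preprocessing contract
  (gene/cell filters, 2% total-count trims, log transform, HVG selection,
  PCA) is specified and tested.
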