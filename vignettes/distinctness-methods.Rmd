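---
title: "Statistical methods for pooled-DNA variety distinctness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for pooled-DNA variety distinctness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolDUS)
```

## The problem

A candidate variety of an outbred forage crop can only be registered if it is
*distinct* from registered varieties. For synthetic varieties of
autotetraploid alfalfa, within-variety variation routinely exceeds
between-variety variation for the morphophysiological traits used in DUS
trials, so candidates selected from a common genetic base often fail the
morphological test even when they are genetically differentiated. poolDUS
implements the complementary molecular route: each population is genotyped as
a few replicate bulks of ~200 pooled plants, each bulk yielding per-locus
allele frequencies, and distinctness is assessed statistically from those
frequency profiles.

The package evaluates four molecular criteria and a conventional
morphophysiological analysis, plus a concordance layer relating the two, and
ships a synthetic-data generator that reproduces the sampling design so every
criterion can be exercised and calibrated without external data.

## The synthetic-data generator

`simulate_population_frequencies()` uses a Balding–Nichols star model: each
locus has an ancestral frequency $p_0 \sim U(0.05, 0.95)$ and each
population's frequency is drawn from
$\mathrm{Beta}\!\big(p_0\tfrac{1-F}{F},\,(1-p_0)\tfrac{1-F}{F}\big)$, so
$E[p] = p_0$ and $\mathrm{Var}[p] = F\,p_0(1-p_0)$. $F$ is the standard
Fst-style divergence knob; $F = 0$ makes populations exact clones of the base
(the null model used for calibration). This is the textbook generative model
for populations "selected from the same genetic base"; no linkage, selection
or pedigree structure is simulated.

`simulate_bulks()` then emulates the measurement chain: a bulk's pool
frequency is a binomial draw of `ploidy * n_plants_per_bulk` allele copies
(default $4 \times 200$ — alfalfa is autotetraploid), per-cell read depth is
negative-binomial around `mean_depth` (64 emulates GBS, 596 a targeted
amplicon panel; dispersion `depth_dispersion = 5` keeps the GBS depth
distribution visibly overdispersed), alternate reads are binomial at the pool
frequency, and cells are missing completely at random at `missing_rate`
(default 5%). MCAR is a simplification: real GBS missingness is
depth- and locus-correlated, so passing filter-calibration tests here does
not certify behaviour under informative missingness.

`simulate_traits()` builds the plot table of a randomized complete block
trial (5 blocks, 22 plants per plot): plot value = grand mean + population
effect + block effect + plot error + the mean of 22 plant deviations.
Proportion traits (flower colours) are plant-level Bernoulli draws whose
probability combines population, block and plot effects on the logit scale,
so a zero base frequency stays exactly zero. Block effects share the
plot-error SD — the source trial reports no variance components, so the
trait calibration targets are property-based (type-I rate, power), not
value-matched. `default_trait_spec()` mirrors a 10-trait alfalfa DUS trial
with four informative traits (onset of flowering, two flower-colour
proportions, leaflet length); the remaining six are pure noise, emulating
populations that share autumn dormancy, growth habit and vigour.

Divergence heterogeneity matters for one analysis. With a single shared $F$,
every true population pair distance has the same expectation, so the
between-pair *pattern* of distances is pure finite-locus noise and two
independently read marker panels cannot agree on it (measured Mantel
r ≈ 0.8 at 64× depth, at any marker count, because drift and read noise both
scale as 1/loci). Real population sets are heterogeneous — mass selection
barely moves the base while progeny-based selection of a dozen parents moves
it a lot — and that spread of divergences is what carries the high
between-panel concordance observed in practice. `heterogeneous_fst()`
(0.02–0.10 across 11 populations) is therefore the configuration used for
the concordance analysis.

## Reading, filtering and imputing pooled counts

`freq_from_counts()` turns ref/alt read counts into alternate-allele
frequencies, keeping the per-cell depth; depth 0 means missing.
`apply_filter()` applies, in a fixed order: (1) cells under `min_reads` are
masked missing; (2) loci whose missing fraction then exceeds `max_missing`
are dropped; (3) loci whose minor allele frequency — the minor side of the
raw mean frequency over all samples, unweighted by depth — is at or below
`maf_min` (default 0.05) are dropped. The order is a package decision: depth
masking changes the missing rate, so it must precede the missing-rate
filter; MAF is computed on raw (unimputed) data under the simplest reading
of "average frequency over all samples". `filter_grid()` crosses
`min_reads` ∈ {10, 20, 30, 40} with `max_missing` ∈ {1, 5, 10, 20, 30}% —
the 20 standard configurations. An empty surviving panel is a warning plus a
0-locus matrix, never a crash.

`impute_freq()` completes the matrix on the continuous frequency domain:
`"mean"` substitutes per-locus means (fast baseline); `"rf"` iterates
random-forest regressions per incomplete locus on its `k_predictors = 50`
most-correlated complete loci until the mean absolute change drops below
1e-4 or 10 passes. Predictor restriction and the convergence rule are
package choices sized for ~33 samples × 10⁴ loci; imputed values are clipped
to [0, 1].

## Morphophysiological distinctness

`rcb_anova()` fits the balanced two-way fixed-effects model
(population + block) by the direct sum-of-squares decomposition and, only
when the overall population effect is significant at `gate_alpha = 0.05`,
performs protected Fisher LSD comparisons at `lsd_alpha = 0.01`:
$|\bar y_i - \bar y_j| > t_{0.995,\,df_e}\sqrt{2\,\mathrm{MSE}/b}$.
Proportion traits get the angular transform $\arcsin\sqrt{p}$ (radians, no
small-sample Bartlett adjustment; a plot proportion of 0 maps to 0). Block
is treated as fixed. The growth-habit score (1–9 ordinal scale) bypasses
ANOVA: `habit_rule()` declares a pair distinct when means differ by strictly
more than 1.5 units. Shapiro–Wilk normality of plot-level ANOVA residuals is
reported by `normality_check()` as a diagnostic only and never gates the
pipeline. Numerical note: the error SS is computed by subtraction, so a
value below 1e-12 of the total SS is snapped to 0; in that degenerate case
the LSD is exactly 0 and any unequal pair is distinct.

## Criterion 1 — PCA + sequential per-axis ANOVA

`pca_scores()` mean-centres loci (no variance scaling — frequencies share a
scale; a switch exists) and decomposes by SVD; numerically zero axes are
dropped. `sequential_axis_test()` walks the axes in order of explained
variance: a one-way ANOVA of the axis scores by population (bulks as
replicates) is followed by all-pairs LSD at `alpha = 0.01`. The LSD is
*unprotected* by default — distinctness rests on "at least one LSD at
P < 0.01" — with a protected variant behind `protected = TRUE`. The scan
stops after `stop_after = 3` consecutive axes that flag nothing. The
stopping phrase "no population difference for three subsequent axes" admits
two readings; the default counts an axis as informative when it separates a
*not-yet-distinct* pair, and `stopping = "any_pair"` implements the stricter
reading. Both terminate; the default can only stop earlier. No familywise
correction is applied across axes by design — the sequential scan's type-I
inflation is a property of the method and is measured (not hidden) by the
package's null simulations: the single-axis LSD false-positive rate sits at
the nominal 1%, while the full scan accumulates roughly the per-axis rate
times the number of informative axes examined.

## Criterion 2 — per-pair PCA + leave-one-out LDA

For each of the 55 pairs, `pair_pca()` fits a PCA once on the six bulks
(up to five axes); `loo_lda()` then holds out each bulk in turn, fits a
two-class linear discriminant with pooled within-class covariance and equal
priors on the remaining five, and classifies the held-out bulk using the
first k axes (k = 1..5 swept by `sweep_pairs()`). A pair is distinct at a
given k only if all six bulks classify correctly. Fitting the PCA before
the loop leaks a little information from the held-out sample; that matches
the description the procedure comes from, and `refit_per_fold = TRUE` gives
the strict variant. With five training points the within-class df is 3, so
for k > 3 the pooled covariance is singular: a diagonal ridge
`1e-6 · trace/k` is added before inversion. LDA is affine-invariant given a
nonsingular covariance, so centring/scaling of scores is immaterial except
on the ridge path. Prediction ties (possible on degenerate data) resolve to
the alphabetically first label; a pair with zero informative axes counts
zero correct rather than erroring.

## Criterion 3 — Nei distance + pairwise AMOVA

`nei_distance()` implements the 1972 standard distance for biallelic
frequency profiles, $D = -\ln\!\big(J_{xy}/\sqrt{J_xJ_y}\big)$ with both
alleles contributing to each identity sum; complete fixation for opposite
alleles at every locus yields an infinite distance, flagged rather than
crashed. `amova_pair()` partitions squared bulk-level distances into
among/within components (bulks are the only available permutation units),
computes Phi_ST (a negative among-group component is clamped to 0 and
flagged), and tests the among-group SS by permuting the bulk-to-population
assignment. Whenever the number of distinct assignments is at most `nperm`,
the distribution is enumerated exhaustively — at the 3 + 3 design that is
C(6,3) = 20 assignments in 10 complementary classes, so the smallest
achievable p is 2/20 = 0.1. The Monte-Carlo fallback (add-one rule) only
engages for larger designs. This floor is the analytically forced reason
the AMOVA criterion can never declare distinctness at P < 0.05 with three
bulks, while four bulks (floor 2/70 ≈ 0.029) make it achievable — the
package reproduces both facts structurally, independent of the data.

## Criterion 4 — UPGMA + multiscale-bootstrap AU support

`sample_distance()` offers the correlation metric (1 − Pearson r between
bulk profiles; the default) and Euclidean. `upgma()` merges the closest
clusters with size-weighted average linkage at height d/2; ties break on the
lexicographically smallest pair of minimum leaf labels, making the tree
invariant to input order. `multiscale_au()` resamples loci with replacement
at ten scales (0.5–1.4 of the locus count; the grid is configurable),
B = 1000 trees per scale, records each observed clade's bootstrap
probability per scale, and fits the signed-distance/curvature decomposition
$z_r = v\sqrt{r} + c/\sqrt{r}$, $z_r = \Phi^{-1}(1 - \mathrm{BP}_r)$, by
weighted least squares (binomial weights); AU $= 1 - \Phi(v - c)$. Scales
where the clade appeared in none or all resamples are excluded from the
fit: a flat all-1 (or all-0) profile carries no curvature information and
would otherwise drag AU toward 0.5 for exactly the clades that are most
strongly supported; such profiles pin AU to the matching clamp,
$1/(B{+}1)$ or $1 - 1/(B{+}1)$. `distinct_by_cluster()` declares a
population completely distinct when some internal node's leaf set equals
exactly its replicate set (no partial matching) with AU ≥ 0.95.

## Concordance between information layers

`population_layer_distance()` forms population-level Euclidean distances:
marker layers average the replicate bulk vectors per population (the source
procedure does not say how; averaging is the natural replicate summary);
trait layers use per-population means of the traits with significant
overall variation, standardized across populations because units differ
(a `standardize = FALSE` switch keeps the raw variant). `mantel_test()`
correlates off-diagonal entries and permutes rows/columns of the second
matrix simultaneously with the add-one rule, default 10,000 permutations.
At n = 11 populations the null Mantel r has an SD near 0.24, so
single-realization "no correlation" statements are noisy; the package's own
concordance checks therefore average the trait-vs-marker r over five
independent trait realizations while keeping the wide ±0.3 bound.

## Pipeline and problem sizes

`run_distinctness()` sweeps criteria 1–2 over the full 20-configuration
grid and runs AMOVA, clustering and Mantel at one fixed well-discriminating
configuration (min 30 reads, max 10% missing) — reproducing the asymmetry
of the procedure it implements. The summary reports, per criterion ×
configuration, distinct pairs of 55 and completely distinct populations of
11; the cluster criterion reports populations only, since it makes no
pairwise comparisons.

The package's tests and acceptance script use 11 populations × 3 bulks ×
1500 markers for power and ordering checks (ten independent runs), 1000
null simulations for LSD calibration, B = 1000 bootstrap replicates for AU
support, and exhaustive AMOVA enumeration; these sizes give Monte-Carlo
standard errors comfortably below the margins being tested while keeping a
full run to a few minutes.

## Known limitations

- The generator's loci are independent: no linkage disequilibrium, no
  selection, no pedigree; divergence is a one-parameter star model.
- MCAR missingness and a single negative-binomial depth law understate the
  structure of real GBS dropout.
- AMOVA is the two-group case only; the multi-level form is out of scope.
- The consensus-tree construction across marker panels is not implemented
  (the pipeline is simply run once per panel); its published description is
  not specific enough to reproduce.
- The discriminant criterion's default PCA-before-LOO choice mildly
  overstates separability on tiny samples; use `refit_per_fold = TRUE` for
  the conservative variant.
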