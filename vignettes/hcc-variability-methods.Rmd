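---
title: "Methods: partitioning hair-cortisol variability in pig cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioning hair-cortisol variability in pig cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hccvar)
```

## The problem and the data model

Hair cortisol concentration (HCC, pg of cortisol per mg of hair) integrates
weeks to months of cortisol secretion and is used as a long-term stress
biomarker in livestock. The designs this package targets sample a fixed
number of finishing pigs per batch (a group raised together and measured at
one visit), two batches per farm several months apart, across a cohort of
farms. Three questions structure the analysis: how the variance splits
between farms, batches within farm, and pigs; whether farms form profiles;
and how many pigs per batch suffice to characterize a batch.

A cohort is a long table of `(farm_id, batch_id, pig_id, hcc)` records.
Identifiers are opaque strings — batch labels "1"/"2" are categories, not
quantities. Invariants enforced at construction: HCC positive and finite,
keys unique, and every (farm, batch) cell holding at least two pigs so an
SD exists. Unbalanced cells are supported (the reference design loses 10
pigs to early slaughter). Values below the assay detection floor
(0.13 pg/mg for a typical salivary-cortisol ELISA applied to 35–40 mg of
hair) are accepted with a warning rather than censored: reference field
data report minima well above the floor and no censoring rule, so silently
truncating would be the more surprising behavior.

All descriptive SDs use the sample convention (denominator n − 1). The two
deliberate exceptions — population scaling in the PCA standardization and
in the quantitative v.test — are the conventions of the cluster-description
methodology those statistics come from, and are what reproduces published
v values; both are noted where they occur.

## Variance partition

The model is a fixed-effects two-way ANOVA,

$$y_{fbp} = \mu + \beta_b + \phi_f + (\beta\phi)_{fb} + \varepsilon_{fbp},$$

fitted with *sequential* (Type I) sums of squares in the fixed order batch
→ farm → batch:farm. In a perfectly balanced design the order would be
irrelevant; with a few pigs missing it matters slightly, so the order is
frozen to the order the model is written in and documented. Effect sizes
are $\eta^2_t = SS_t / SS_{total}$ for every term *including residuals*, so
the four values always sum to 1 and read directly as "fractions of
variability explained". No transformation is applied to the raw
concentrations — the analysis tradition here models raw pg/mg even though
the marginal distribution is right-skewed — and the residual diagnostics
(Shapiro–Wilk; Levene on the 40 cells, Brown–Forsythe median centering by
default, mean centering by option; QQ coordinates) therefore *inform*
rather than gate: the pipeline proceeds and the flags travel with the
output. A cell pattern in which some farm lacks a batch is refused
explicitly (rank-deficient for the interaction), and an all-constant
response is refused as "zero total variance" rather than returning η² of
0/0.

Within-farm batch contrasts use the Tukey–Kramer studentized-range
statistic with the residual mean square of the full interaction model and
unequal cell sizes. The comparison family is, by default, *all pairs of
(farm, batch) cell means* (40 cells in the reference design): the 20
reported within-farm contrasts are drawn from that family. This is the
family the standard post-hoc route on the interaction term produces;
because the published analysis is not explicit about the family, a
restricted `family = "within_farm"` option (each contrast its own
two-mean family, equivalent to an unadjusted t-test through the
$q = t\sqrt{2}$ identity) is available.

Cohen's *d* is computed from summary statistics with the *combined-sample*
denominator: with $m = (n_1 m_1 + n_2 m_2)/(n_1+n_2)$,

$$s^2_{comb} = \frac{n_1\,(s_1^2 + (m_1-m)^2) + n_2\,(s_2^2 + (m_2-m)^2)}{n_1+n_2},
\qquad d = |m_1 - m_2| / s_{comb}.$$

The choice is empirical: the pooled *within*-batch SD does not reproduce
published effect-size tables for this design (a farm with batch means 13.7
and 54.5 and SDs 3.7 and 24.1 would give ≈ 2.4, not the printed 1.5),
while the combined-sample SD reproduces 19 of 20 rows of the reference
table to ±0.1. The one remaining row (recomputed 0.74 vs printed 0.6) is
irreconcilable under every denominator convention we tried and is treated
as a misprint; the corresponding acceptance assertion is deliberately left
failing rather than widened.

## Farm typology

Each farm contributes four *active* variables: mean and SD of HCC in each
of its two batches. The matrix is standardized with *population* scaling
(denominator N) and decomposed by eigendecomposition of the correlation
matrix; component signs are fixed by making each component's
largest-magnitude loading positive, so scores are reproducible across
platforms. Ward agglomerative clustering (`ward.D2` on Euclidean
distances) runs on the scores of **all four** components: with only four
variables there is no noise-truncation argument, truncation is therefore a
choice we do not make, and keeping all components makes Ward distances
equal distances in the standardized variable space. `k = "auto"` cuts the
tree at the largest relative jump in merge heights (the biggest gain in
between-cluster inertia); the reference typology is obtained with a fixed
`k = 3`. An optional k-means consolidation pass (Lloyd iterations from the
hierarchical centroids, hence deterministic) is OFF by default so the
reported partition is exactly the tree cut.

Cluster characterization uses the v.test. Quantitative:

$$v = \frac{\bar x_k - \bar x}{\sqrt{\dfrac{s^2}{n_k}\,\dfrac{N-n_k}{N-1}}},$$

with $s^2$ the population variance of the N farm values — the
finite-population correction and the N-denominator are both required to
reproduce published values from rounded table inputs, and v is invariant
under affine rescaling of the variable. Categorical levels are referred to
the hypergeometric law of their in-cluster count; the reported p is the
*smaller tail* ($P(X \ge x)$ or $P(X \le x)$) and
$v = \mathrm{sign} \cdot \Phi^{-1}(1 - p/2)$, positive when the level is
over-represented. That convention — rather than doubling the tail before
the quantile transform — is what reproduces published supplementary-variable
values (2.41 for a 2-of-20 level fully inside a 3-farm cluster, −1.99 for
a 17-of-20 level with a single farm inside it). Under random partitions
the quantitative v is approximately standard normal, which the test suite
checks by simulation.

## Subsample study

For a batch with values $x_1,\dots,x_n$ (mean $\mu_n$, SD $\sigma_n$,
denominators n − 1) and each subsample $i$ of size $j$:

$$\Delta_{i,j} = \frac{\mu_{i,j} - \mu_n}{\mu_n}, \qquad
\Delta'_{i,j} = \frac{\sigma_{i,j} - \sigma_n}{\sigma_n}.$$

Subsample SDs also use j − 1: besides matching the descriptive convention,
it yields the exact simple-random-sampling-without-replacement identity
$\mathbb{E}_i[\sigma^2_{i,j}] = \sigma^2_n$, asserted in the tests to
1e−10 over full enumerations, alongside the exact zero mean of
$\Delta$ over all subsets. Enumeration is lexicographic and streams in
compiled code with O(j) state; values are centered on the batch mean
before accumulation to keep those identities near machine precision.
Exhaustive mode is capped at `max_enumeration = 2e6` subsets per
(batch, j) — chosen so every classic size of a 24-pig batch stays exact
(max C(24,10) = 1,961,256) while bounding runtime — beyond which a seeded
Monte Carlo fallback engages with a logged notice. Percentiles use linear
interpolation between order statistics (`quantile` type 7, the R default);
no convention is published for this statistic, so the choice is documented
and configurable at the level of the percentile list. Per-batch
percentiles are computed first and then averaged across batches — the
"mean of the batch percentiles", not a pooled-distribution percentile,
because the study's deliverable is the typical batch's error band.
Batches smaller than a requested j skip that size with a notice; Monte
Carlo seeds fan out deterministically per (batch, j) from the single
configured seed.

## Synthetic cohorts

The generator states a world matching the reference design: 20 farms, two
batches per farm, 24 pigs per batch with 10 pigs removed two each from
five cells on five distinct farms; grand mean 25.9 pg/mg, total SD 16.2;
variance fractions farm 0.241, batch 0.031, interaction 0.163, residual
0.565. Two noise families:

* `additive_gaussian` — the ANOVA model itself. Effect vectors are drawn
  Gaussian, then **centered and rescaled so their realized mean square
  equals fraction × total variance** (the interaction matrix is
  double-centered). This is a deliberate design decision: with only two
  batch levels, uncentered iid draws leak roughly half of the interaction
  variance into the farm term, and *no* η² decomposition could then
  recover the stated split — the expected gap (≈ 0.07) exceeds the ±0.05
  recovery band the package tests itself against. With the constraint,
  mean η̂² over 200 seeds recovers every fraction within ±0.03. The cost
  is that effect magnitudes are exact rather than χ²-distributed across
  replicates; for a generator whose purpose is known ground truth we
  consider that a feature. Additive noise can cross zero at the
  calibrated parameters (about 5 % of draws); such values are retained
  with a warning because truncating them would bias the recovery tests —
  real assay data must still be positive at the reader.
* `lognormal` — the same linear decomposition on the log scale, with
  total log-variance $\tau^2 = \log(1 + cv^2)$ and location
  $\log(\text{grand mean}) - \tau^2/2$ so the realized arithmetic moments
  approximate the targets (moment matching is approximate by design;
  equality assertions live in the additive family only). This family is
  the default for `emulate_study_design()` because it reproduces the two
  qualitative signatures of the field data: right skew and a strong
  positive coupling of batch SD with batch mean (realized correlation
  ≈ 0.9 across the 40 batches, vs 0.83 reported from the field).

What the generator does **not** emulate: pen structure within batches
(pens exist in the field protocol but are never modeled in the analysis),
seasonal order of the two visits, and any causal link from management
practices to HCC — supplementary metadata for typology tests is sampled
independently of the concentrations. A green parameter-recovery test
therefore establishes that the estimator recovers the variance structure
*of this model*, not that the model exhausts real farms.

## Numerical and interface choices

* Determinism: every stochastic path takes an explicit integer seed; the
  pipeline fans a single top-level seed out to the stages and logs it in
  the manifest; generators save and restore the global RNG state.
* CSV artifacts round to 6 significant digits, which makes re-runs
  byte-identical; display rounding (1 decimal, table style) happens only
  in the rendered report.
* Ties and signs: PCA signs fixed by the largest-loading rule; cluster
  labels renumbered by first occurrence in sorted farm order, making the
  partition invariant to input order.
* Degenerate inputs are explicit errors, not NaNs: all-equal responses
  (zero total SS), a farm missing a batch, zero-variance PCA columns,
  zero batch SD in the subsample study, a cluster containing every farm.
  A Levene call on cells with *identical* absolute deviations returns
  statistic 0 / p 1 instead of an unstable 0/0 F ratio.
* The enumeration cap (2e6) and the Shapiro–Wilk range (3 ≤ n ≤ 5000,
  inherited from the test itself) are the only hard size limits; both are
  reported, never silently absorbed.

## Known limitations

* The typology's supplementary-variable characterization can only be
  validated structurally (against exact hypergeometric oracles and
  reconstructed scenarios): the per-farm practice table behind published
  v values is not part of the package's inputs.
* Published effect-size tables derived from raw data can differ from
  recomputations off rounded summaries by up to ~0.05; one reference row
  exceeds any such explanation and is treated as a misprint (see the
  acceptance suite).
* The restricted Tukey family option covers the plausible alternative
  reading of the published post-hoc procedure, but p-values under it are
  unadjusted for the 20-farm multiplicity.
* Fixed-effects η² is descriptive; no REML/mixed-model variance-component
  estimation is attempted, deliberately.
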