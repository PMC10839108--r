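# hccvar

Variance analysis of hair cortisol concentration (HCC) in pig cohorts
sampled batch-wise across commercial farms.

Hair cortisol is a non-invasive biomarker of long-term stress exposure: it
accumulates during hair growth, so a clipped sample taken at the end of the
finishing period integrates weeks to months of cortisol secretion. Field
designs for this biomarker sample a fixed number of pigs per batch, two
batches per farm, across many farms — and the central statistical questions
are (i) how HCC variance splits between farms, batches within farm, and
individual pigs, (ii) whether farms form interpretable profiles, and
(iii) how many pigs per batch are enough to characterize a batch. `hccvar`
implements that full analysis as a tested, reusable pipeline, for
veterinary epidemiologists and animal-welfare researchers working with
pig-level concentration tables (pg cortisol / mg hair).

## What it computes

* **Variance partition** — fixed-effects two-way ANOVA,
  `hcc ~ batch + farm + batch:farm`, with *sequential* (Type I) sums of
  squares in that order and effect sizes
  `eta^2_term = SS_term / SS_total` for every term including the residuals
  (so `sum(eta^2) = 1`). Residual diagnostics (Shapiro–Wilk,
  Brown–Forsythe Levene, QQ coordinates), Tukey–Kramer batch contrasts
  within each farm, and the combined-sample Cohen's *d*
  `|m1 - m2| / s_combined`, where `s_combined` is the SD of the pooled
  two-batch sample reconstructed from summary statistics.
* **Farm typology** — per farm, the four active variables (mean and SD of
  HCC in each batch) are standardized (population scaling) and decomposed
  by PCA; Ward clustering on the component scores partitions the farms;
  clusters are characterized by v.test statistics: for a quantitative
  variable `v = (xbar_k - xbar) / sqrt((s^2/n_k) (N-n_k)/(N-1))`, for a
  categorical level a signed normal quantile of the hypergeometric tail of
  its in-cluster count.
* **Subsample study** — for each batch of n pigs, *all* `C(n, j)`
  subsamples of sizes j (default 5, 10, 15, 20 of 24) are scored by
  `delta = (mean_j - mean_n) / mean_n` and
  `delta' = (sd_j - sd_n) / sd_n`; per-batch 5th/50th/95th percentiles
  and their cross-batch means quantify how sample size limits batch
  characterization. Exhaustive enumeration streams in compiled code
  (about 3.3 million subsets per 24-pig batch in under a second); a
  seeded Monte Carlo fallback handles larger designs.
* **Synthetic cohorts** — a generator with known hierarchical variance
  components (farm, batch, interaction, residual; additive-Gaussian or
  lognormal noise), calibrated by default to the reference field design
  (20 farms x 2 batches x 24 pigs, 10 pigs missing, grand mean 25.9 pg/mg,
  SD 16.2, variance split 24.1 / 3.1 / 16.3 / 56.5 %), so every stage can
  be tested against ground truth.

## Worked example

The package ships the reference study's per-batch summary table
(`inst/extdata/reference_batch_summaries.csv`: 20 farms x 2 batches, mean and
SD per batch, n = 24).

```r
library(hccvar)
t2 <- read.csv(system.file("extdata", "reference_batch_summaries.csv",
                           package = "hccvar"),
               colClasses = c(farm_id = "character", batch_id = "character"))

# effect size of the batch contrast on farm E
s <- t2[t2$farm_id == "E", ]
cohens_d_combined(s$mean[1], s$sd[1], s$n[1], s$mean[2], s$sd[2], s$n[2])
#> [1] 1.527533

# dispersion grows with the batch mean
mean_sd_regression(t2)$pearson_r
#> [1] 0.8339268

# farm typology
farm_typology(t2, k = 3)
#> Farm typology: 20 farms, 3 clusters
#> PCA variance explained (%): 51.51, 39.96,  6.36,  2.18
#>   cluster 1: A, B, G
#>   cluster 2: C, F, J, L, M, N, P, Q, R, S, T
#>   cluster 3: D, E, H, I, K, O
```

The Cohen's *d* of 1.53 says farm E's two batches differ by about 1.5
combined-sample SDs; r = 0.83 is the batch-level mean–SD coupling; the
first two components carry 91.5 % of the active-matrix variance, and the
three-cluster cut isolates farms A, B, G — the low, homogeneous-HCC
profile.

A full synthetic run, ANOVA included:

```r
co <- emulate_study_design(seed = 1)
co
#> HCC cohort: 950 pigs, 20 farms, 2 batches per farm (labels: 1, 2)
#> hcc (pg/mg): mean 26.32, sd 15.41, range [3.566, 124.1]
fit_two_way_anova(co)
#> Two-way ANOVA of HCC (sequential SS: batch -> farm -> batch:farm)
#>        term     ss  df mean_sq     f         p eta_squared eta_squared_pct
#>       batch   5647   1  5647.2 36.57 2.146e-09     0.02506           2.506
#>        farm  44723  19  2353.8 15.24 5.402e-43     0.19847          19.847
#>  batch:farm  34449  19  1813.1 11.74 1.832e-32     0.15288          15.288
#>   residuals 140518 910   154.4    NA        NA     0.62359          62.359
```

The realized eta-squared percentages sit near the generator's calibrated
split (lognormal noise shifts them slightly on the linear scale; the
additive family recovers them to within ±0.03 averaged over seeds).

## Command line

```sh
Rscript inst/cli/hccvar all --input synthetic --seed 7 --out out/
Rscript inst/cli/hccvar subsample --input cohort.csv --sizes 5,10,15,20 --out out/
```

`run_pipeline()` / the CLI write table- and figure-ready CSVs plus a
`manifest.json` (MD5 per artifact, resolved config, stage timings) and a
`report.md` rendered by `render_report()`. Outputs are byte-identical
across runs with the same seed.

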