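Package: hccvar
Title: Variability of Hair Cortisol Concentration in Pig Cohorts
Version: 0.1.0
Authors@R:
    person("hccvar", "maintainers", email = "maintainers@hccvar.example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for hair cortisol concentration (HCC) measured
    on finishing pigs sampled in batches across commercial farms. Partitions
    HCC variance between farms, batches and individual pigs by sequential
    two-way analysis of variance with eta-squared effect sizes, builds a farm
    typology by standardized principal component analysis followed by Ward
    hierarchical clustering with v.test cluster characterization, and
    quantifies the effect of within-batch sample size by exhaustive
    enumeration of all subsamples with relative differences of means and
    standard deviations. Includes a synthetic cohort generator with known
    hierarchical variance components so every stage can be tested against
    ground truth, plus a command-line pipeline runner emitting table- and
    figure-ready artifacts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
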