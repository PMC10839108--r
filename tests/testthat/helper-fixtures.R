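# Shared fixtures, built in code or read from the package's extdata.

# Per-batch summary statistics of the 20-farm reference study (printed
# field-study table shipped with the package), plus the printed effect
# sizes and post-hoc significance column.
reference_summaries <- function() {
  read.csv(system.file("extdata", "reference_batch_summaries.csv",
                       package = "hccvar"),
           colClasses = c(farm_id = "character", batch_id = "character"))
}

reference_printed <- function() {
  read.csv(system.file("extdata", "reference_printed_effects.csv",
                       package = "hccvar"),
           colClasses = c(farm_id = "character"))
}

# Minimal balanced toy cohort: 2 farms x 2 batches x 2 pigs, hand-listed.
toy_cohort <- function() {
  new_cohort(data.frame(
    farm_id = rep(c("A", "B"), each = 4),
    batch_id = rep(rep(c("1", "2"), each = 2), 2),
    pig_id = rep(c("p1", "p2"), 4),
    hcc = c(10, 12, 20, 26, 30, 34, 31, 37)))
}

# Mid-sized random cohort for property tests (additive family, mild
# effects so values stay positive).
random_cohort <- function(seed, n_farms = 4, n_pigs = 6,
                          fractions = c(farm = 0.2, batch = 0.1,
                                        interaction = 0.1, residual = 0.6)) {
  p <- simulation_params(n_farms = n_farms, n_pigs_per_batch = n_pigs,
                         grand_mean = 50, total_sd = 8,
                         variance_fractions = fractions,
                         noise_family = "additive_gaussian", seed = seed)
  generate_cohort(p)$cohort
}

write_temp_cohort <- function(cohort) {
  path <- tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  path
}
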