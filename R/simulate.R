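# Synthetic cohort generator -------------------------------------------------
#
# Cohorts with known hierarchical variance structure: a farm main effect, a
# batch main effect shared across farms, a farm-specific batch deviation
# (interaction) and pig-level residual noise. Two noise families:
#   * additive_gaussian — the linear ANOVA model itself; exact closed-form
#     expected sums of squares, used for parameter-recovery tests.
#   * lognormal — the same linear predictor on the log scale with
#     moment-matched location/scale, producing the right skew and the
#     positive batch mean--SD coupling seen in field HCC data.

#' Simulation parameters for a synthetic HCC cohort
#'
#' Defaults reproduce the field-study design the package targets: 20 farms,
#' two batches per farm, 24 pigs per batch, grand mean 25.9 pg/mg, total SD
#' 16.2 pg/mg, and variance split farm 24.1%, batch 3.1%, interaction 16.3%,
#' residual 56.5%.
#'
#' @param n_farms,n_batches_per_farm,n_pigs_per_batch design dimensions.
#' @param grand_mean,total_sd target marginal moments of HCC, pg/mg.
#' @param variance_fractions named non-negative fractions for `farm`,
#'   `batch`, `interaction`, `residual`; must sum to 1.
#' @param noise_family `"additive_gaussian"` or `"lognormal"`.
#' @param dropout data.frame with columns `farm`, `batch` (1-based design
#'   indices) and `count`: pigs removed from those cells. NULL for none.
#' @param detection_floor truncate values from below at this concentration,
#'   or NULL (default) for no truncation.
#' @param seed integer RNG seed.
#' @return validated list of class `hcc_sim_params`.
#' @export
simulation_params <- function(n_farms = 20L, n_batches_per_farm = 2L,
                              n_pigs_per_batch = 24L,
                              grand_mean = 25.9, total_sd = 16.2,
                              variance_fractions = c(farm = 0.241,
                                                     batch = 0.031,
                                                     interaction = 0.163,
                                                     residual = 0.565),
                              noise_family = c("additive_gaussian",
                                               "lognormal"),
                              dropout = NULL, detection_floor = NULL,
                              seed = 1L) {
  noise_family <- match.arg(noise_family)
  stopifnot(n_farms >= 1, n_batches_per_farm >= 1, n_pigs_per_batch >= 2)
  if (!(grand_mean > 0)) stop("grand_mean must be positive")
  if (!(total_sd > 0)) stop("total_sd must be positive")
  need <- c("farm", "batch", "interaction", "residual")
  if (!all(need %in% names(variance_fractions))) {
    stop("variance_fractions must name: ", paste(need, collapse = ", "))
  }
  variance_fractions <- variance_fractions[need]
  if (any(variance_fractions < 0)) stop("variance fractions must be >= 0")
  if (abs(sum(variance_fractions) - 1) > 1e-8) {
    stop("variance fractions must sum to 1 (got ",
         format(sum(variance_fractions)), ")")
  }
  if (!is.null(dropout)) {
    dropout <- as.data.frame(dropout)
    stopifnot(all(c("farm", "batch", "count") %in% names(dropout)))
    if (any(dropout$count >= n_pigs_per_batch - 1L)) {
      stop("dropout would leave a cell with fewer than 2 pigs")
    }
  }
  structure(list(n_farms = as.integer(n_farms),
                 n_batches_per_farm = as.integer(n_batches_per_farm),
                 n_pigs_per_batch = as.integer(n_pigs_per_batch),
                 grand_mean = grand_mean, total_sd = total_sd,
                 variance_fractions = variance_fractions,
                 noise_family = noise_family, dropout = dropout,
                 detection_floor = detection_floor, seed = as.integer(seed)),
            class = "hcc_sim_params")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Additive family: `hcc = grand_mean + F_f + B_b + I_fb + e`. Each effect
#' vector is drawn Gaussian, then centered (the sum-to-zero convention of
#' the ANOVA parametrization; the interaction matrix is double-centered) and
#' rescaled so its realized mean square equals `fraction * total_sd^2`. The
#' centering/rescaling is what makes the generating fractions estimable from
#' a single realization: with only two batch levels, uncentered iid draws
#' would leak about half of the interaction variance into the farm term and
#' no eta-squared decomposition could recover the stated split. The batch
#' effect `B_b` is shared by all farms; the interaction `I_fb` is
#' farm-specific; residuals are iid Gaussian. Lognormal family: the same
#' decomposition built on the log scale with total log-variance
#' `log(1 + cv^2)` and location `log(grand_mean) - tau2/2`, so the realized
#' arithmetic mean and SD approximate the targets while the distribution is
#' right-skewed and batch SD grows with batch mean.
#'
#' @param params an [simulation_params()] object.
#' @return list of class `hcc_simulation`: `cohort` (an `hcc_cohort`) and
#'   `ground_truth` (realized farm/batch/interaction effects and the
#'   generating parameters).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "hcc_sim_params"))
  p <- params
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(p$seed)

  farms <- if (p$n_farms <= 26) LETTERS[seq_len(p$n_farms)] else {
    sprintf("F%02d", seq_len(p$n_farms))
  }
  batches <- as.character(seq_len(p$n_batches_per_farm))

  if (p$noise_family == "additive_gaussian") {
    total_var <- p$total_sd^2
    location <- p$grand_mean
  } else {
    cv <- p$total_sd / p$grand_mean
    total_var <- log(1 + cv^2)          # log-scale variance, moment matched
    location <- log(p$grand_mean) - total_var / 2
  }
  v <- p$variance_fractions * total_var
  center_scale <- function(x, target) {
    x <- x - mean(x)
    ms <- mean(x^2)
    if (target == 0 || ms == 0) x * 0 else x * sqrt(target / ms)
  }
  farm_eff <- setNames(center_scale(rnorm(p$n_farms), v[["farm"]]), farms)
  batch_eff <- setNames(center_scale(rnorm(p$n_batches_per_farm),
                                     v[["batch"]]), batches)
  int_eff <- matrix(rnorm(p$n_farms * p$n_batches_per_farm),
                    nrow = p$n_farms, dimnames = list(farms, batches))
  int_eff <- int_eff - rowMeans(int_eff)
  int_eff <- sweep(int_eff, 2, colMeans(int_eff))
  ms <- mean(int_eff^2)
  int_eff <- if (v[["interaction"]] == 0 || ms == 0) {
    int_eff * 0
  } else {
    int_eff * sqrt(v[["interaction"]] / ms)
  }

  rows <- vector("list", p$n_farms * p$n_batches_per_farm)
  k <- 0L
  for (f in seq_len(p$n_farms)) {
    for (b in seq_len(p$n_batches_per_farm)) {
      n <- p$n_pigs_per_batch
      lin <- location + farm_eff[f] + batch_eff[b] + int_eff[f, b] +
        rnorm(n, 0, sqrt(v[["residual"]]))
      hcc <- if (p$noise_family == "lognormal") exp(lin) else lin
      k <- k + 1L
      rows[[k]] <- data.frame(farm_id = farms[f], batch_id = batches[b],
                              pig_id = sprintf("P%02d", seq_len(n)),
                              hcc = hcc, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)

  if (!is.null(p$dropout)) {
    for (i in seq_len(nrow(p$dropout))) {
      f <- farms[p$dropout$farm[i]]
      b <- batches[p$dropout$batch[i]]
      idx <- which(df$farm_id == f & df$batch_id == b)
      if (p$dropout$count[i] > length(idx)) {
        stop("dropout exceeds cell size for farm ", f, ", batch ", b)
      }
      drop <- idx[seq(length(idx) - p$dropout$count[i] + 1L, length(idx))]
      df <- df[-drop, , drop = FALSE]
    }
  }
  if (!is.null(p$detection_floor)) {
    df$hcc <- pmax(df$hcc, p$detection_floor)
  }
  cohort <- suppressWarnings(
    new_cohort(df, allow_nonpositive = p$noise_family == "additive_gaussian"))
  structure(list(cohort = cohort,
                 ground_truth = list(farm_effects = farm_eff,
                                     batch_effects = batch_eff,
                                     interaction_effects = int_eff,
                                     variance_fractions = p$variance_fractions,
                                     params = p)),
            class = "hcc_simulation")
}

#' Emulate the reference field-study design
#'
#' 20 farms x 2 batches x 24 pigs, minus 10 pigs removed 2 each from 5
#' distinct (farm, batch) cells on 5 distinct farms (chosen by seed): 950
#' pigs. Uses the lognormal family with the calibrated defaults of
#' [simulation_params()].
#'
#' @param seed integer seed; the same seed always yields the same cohort.
#' @param noise_family forwarded to [simulation_params()].
#' @return an `hcc_cohort` with 950 records.
#' @export
emulate_study_design <- function(seed = 1L, noise_family = "lognormal") {
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  farms_hit <- sample(20L, 5L)
  dropout <- data.frame(farm = farms_hit,
                        batch = sample(2L, 5L, replace = TRUE),
                        count = 2L)
  params <- simulation_params(noise_family = noise_family, dropout = dropout,
                              seed = seed + 1L)
  generate_cohort(params)$cohort
}
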