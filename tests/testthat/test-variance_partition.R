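test_that("sequential SS on a balanced toy equals the projection oracle", {
  co <- toy_cohort()
  fit <- fit_two_way_anova(co)
  ss <- setNames(fit$table$ss, fit$table$term)
  oracle <- oracle_ss_balanced(as.data.frame(co))
  expect_equal(unname(ss["batch"]), unname(oracle["batch"]))
  expect_equal(unname(ss["farm"]), unname(oracle["farm"]))
  expect_equal(unname(ss["batch:farm"]), unname(oracle["interaction"]))
  expect_equal(unname(ss["residuals"]), unname(oracle["residuals"]))
  expect_equal(sum(ss), unname(oracle["total"]))
  expect_equal(sum(fit$table$df), nrow(co) - 1)
})

test_that("eta-squared is a partition of unity on random cohorts", {
  for (seed in 1:5) {
    co <- random_cohort(seed, n_farms = 3 + seed %% 3, n_pigs = 5)
    fit <- fit_two_way_anova(co)
    expect_equal(sum(fit$table$eta_squared), 1, tolerance = 1e-12)
    expect_true(all(fit$table$eta_squared >= 0 &
                      fit$table$eta_squared <= 1))
    # relabeling pigs within cells leaves the SS unchanged
    df <- as.data.frame(co)
    df$pig_id <- ave(df$pig_id, df$farm_id, df$batch_id,
                     FUN = function(x) rev(x))
    fit2 <- fit_two_way_anova(new_cohort(df))
    expect_equal(fit2$table$ss, fit$table$ss)
  }
})

test_that("degenerate and rank-deficient designs raise explicit errors", {
  flat <- new_cohort(data.frame(farm_id = rep(c("A", "B"), each = 4),
                                batch_id = rep(c("1", "1", "2", "2"), 2),
                                pig_id = rep(c("p1", "p2"), 4), hcc = 5))
  expect_error(fit_two_way_anova(flat), "zero total variance")

  df <- as.data.frame(toy_cohort())
  df <- df[!(df$farm_id == "B" & df$batch_id == "2"), ]
  expect_error(fit_two_way_anova(new_cohort(df)), "farm B.*batch 2")
})

test_that("residual diagnostics behave as designed tests", {
  # type-I error of Shapiro-Wilk on genuinely normal residuals
  reject_norm <- vapply(1:50, function(s) {
    co <- random_cohort(s + 100, n_farms = 5, n_pigs = 50)
    d <- residual_diagnostics(fit_two_way_anova(co))
    d$shapiro$p < 0.05
  }, logical(1))
  expect_gte(mean(!reject_norm), 0.9)

  # power against heavy right skew (lognormal residual noise, n = 500)
  reject_skew <- vapply(1:20, function(s) {
    p <- simulation_params(n_farms = 5, n_pigs_per_batch = 50,
                           grand_mean = 25.9, total_sd = 16.2,
                           noise_family = "lognormal", seed = s)
    d <- residual_diagnostics(fit_two_way_anova(generate_cohort(p)$cohort))
    d$shapiro$p < 0.05
  }, logical(1))
  expect_equal(mean(reject_skew), 1)

  # no dispersion differences -> Levene statistic 0
  co <- new_cohort(data.frame(farm_id = rep(c("A", "B"), each = 4),
                              batch_id = rep(c("1", "1", "2", "2"), 2),
                              pig_id = rep(c("p1", "p2"), 4),
                              hcc = c(1, 3, 11, 13, 21, 23, 31, 33)))
  d <- residual_diagnostics(fit_two_way_anova(co))
  expect_equal(d$levene$statistic, 0)
  expect_equal(nrow(d$qq), 8)
})

test_that("manual Tukey-Kramer agrees with stats::TukeyHSD", {
  co <- random_cohort(31, n_farms = 4, n_pigs = 8)
  res <- tukey_batch_comparisons(co)
  dat <- data.frame(hcc = co$hcc,
                    cell = interaction(co$batch_id, co$farm_id))
  hsd <- TukeyHSD(aov(hcc ~ cell, data = dat))$cell
  for (f in attr(co, "farm_ids")) {
    pair <- paste0("2.", f, "-1.", f)
    expect_equal(res$adjusted_p[res$farm_id == f],
                 unname(hsd[pair, "p adj"]), tolerance = 1e-6)
    expect_equal(res$mean_diff[res$farm_id == f],
                 unname(hsd[pair, "diff"]), tolerance = 1e-10)
  }
})

test_that("two-cell family reduces to the t-test via q = t*sqrt(2)", {
  co2 <- random_cohort(77, n_farms = 2, n_pigs = 6)
  res <- tukey_batch_comparisons(co2, family = "within_farm")
  fit <- fit_two_way_anova(co2)
  mse <- fit$table$mean_sq[4]
  df <- fit$table$df[4]
  sm <- batch_summaries(co2)
  for (f in c("A", "B")) {
    s <- sm[sm$farm_id == f, ]
    tstat <- abs(diff(s$mean)) / sqrt(mse * (1 / s$n[1] + 1 / s$n[2]))
    p_t <- 2 * pt(tstat, df, lower.tail = FALSE)
    expect_equal(res$adjusted_p[res$farm_id == f], p_t, tolerance = 1e-9)
  }
})

test_that("identical batch means give adjusted p of 1", {
  co <- new_cohort(data.frame(farm_id = rep(c("A", "B"), each = 6),
                              batch_id = rep(rep(c("1", "2"), each = 3), 2),
                              pig_id = rep(sprintf("p%d", 1:3), 4),
                              hcc = c(9, 10, 11, 8, 10, 12,
                                      19, 20, 21, 18, 20, 22)))
  res <- tukey_batch_comparisons(co)
  expect_equal(res$adjusted_p, c(1, 1))
  expect_false(any(res$significant))
})

test_that("combined-sample Cohen's d matches the reference table", {
  expect_equal(cohens_d_combined(10, 3, 24, 10, 5, 24), 0)
  # reference farms: E -> 1.53, A -> 1.41 (combined-SD oracle values)
  expect_equal(cohens_d_combined(13.7, 3.7, 24, 54.5, 24.1, 24), 1.53,
               tolerance = 0.005)
  expect_equal(cohens_d_combined(4.9, 1.6, 24, 13.7, 6.1, 24), 1.41,
               tolerance = 0.005)
  # symmetry and overflow flag
  expect_equal(cohens_d_combined(13.7, 3.7, 24, 54.5, 24.1, 24),
               cohens_d_combined(54.5, 24.1, 24, 13.7, 3.7, 24))
  expect_warning(d <- cohens_d_combined(5, 0, 24, 5, 0, 24), NA)
  expect_equal(d, 0)
})

test_that("mean-SD regression equals the direct-formula oracle", {
  sm <- data.frame(mean = c(1, 2, 3, 4), sd = c(2, 4, 6, 8))
  expect_equal(mean_sd_regression(sm)$pearson_r, 1)

  set.seed(5)
  sm2 <- data.frame(mean = runif(10, 10, 50), sd = runif(10, 2, 20))
  reg <- mean_sd_regression(sm2)
  expect_equal(reg$pearson_r, oracle_pearson(sm2$mean, sm2$sd),
               tolerance = 1e-12)
  expect_error(mean_sd_regression(data.frame(mean = c(2, 2, 2),
                                             sd = c(1, 2, 3))),
               "zero variance")
})
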