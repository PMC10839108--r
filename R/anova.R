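# Variance partition ---------------------------------------------------------
#
# Fixed-effects two-way ANOVA of HCC on batch, farm and their interaction,
# with sequential (Type I) sums of squares in that fixed order. With a few
# pigs missing the design is mildly unbalanced, so the order matters; it is
# fixed to the order the model is written in and documented. Effect sizes are
# eta^2 = SS_term / SS_total, computed for every term including residuals, so
# they always sum to 1.

#' Fit the two-way HCC analysis of variance
#'
#' @param cohort an `hcc_cohort` with at least 2 farms and 2 batch labels,
#'   every farm observed in every batch, every cell holding >= 2 pigs.
#' @return object of class `hcc_anova`: data.frame `table` (term, ss, df,
#'   mean_sq, f, p, eta_squared for batch, farm, batch:farm, residuals), plus
#'   the residual vector, fitted cell structure and the underlying `lm` fit.
#' @export
fit_two_way_anova <- function(cohort) {
  stopifnot(inherits(cohort, "hcc_cohort"))
  farms <- attr(cohort, "farm_ids")
  batches <- attr(cohort, "batch_ids")
  if (length(farms) < 2) stop("need at least 2 farms")
  if (length(batches) < 2) stop("need at least 2 batch labels")
  cell <- table(factor(cohort$farm_id, farms), factor(cohort$batch_id, batches))
  empty <- which(cell == 0L, arr.ind = TRUE)
  if (nrow(empty) > 0) {
    stop("rank-deficient design: farm ", rownames(cell)[empty[1, 1]],
         " has no pigs in batch ", colnames(cell)[empty[1, 2]])
  }
  ss_total <- sum((cohort$hcc - mean(cohort$hcc))^2)
  if (ss_total == 0) stop("zero total variance: all observations equal")

  dat <- data.frame(hcc = cohort$hcc,
                    batch = factor(cohort$batch_id, batches),
                    farm = factor(cohort$farm_id, farms))
  fit <- lm(hcc ~ batch + farm + batch:farm, data = dat)
  a <- anova(fit)  # sequential SS in model order
  tab <- data.frame(term = c("batch", "farm", "batch:farm", "residuals"),
                    ss = a[["Sum Sq"]], df = a[["Df"]],
                    mean_sq = a[["Mean Sq"]],
                    f = a[["F value"]], p = a[["Pr(>F)"]],
                    stringsAsFactors = FALSE)
  tab$eta_squared <- tab$ss / sum(tab$ss)
  structure(list(table = tab, residuals = unname(stats::residuals(fit)),
                 data = dat, fit = fit, ss_total = sum(tab$ss)),
            class = "hcc_anova")
}

#' @export
print.hcc_anova <- function(x, ...) {
  cat("Two-way ANOVA of HCC (sequential SS: batch -> farm -> batch:farm)\n")
  tab <- x$table
  tab$eta_squared_pct <- 100 * tab$eta_squared
  print(format(tab, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Residual diagnostics for a fitted HCC ANOVA
#'
#' Shapiro--Wilk normality test of the residuals, a Levene-type test of
#' homoscedasticity across the (farm, batch) cells (Brown--Forsythe median
#' centering by default), and normal QQ-plot coordinates. Diagnostics inform;
#' they never stop the pipeline.
#'
#' @param fit an `hcc_anova`.
#' @param levene_center `"median"` (Brown--Forsythe, default) or `"mean"`.
#' @return list of class `hcc_diagnostics`: `shapiro` (statistic, p, or NA
#'   with a flag when n < 3 or n > 5000), `levene` (statistic, df, p),
#'   `qq` (data.frame theoretical/sample), `flags`.
#' @export
residual_diagnostics <- function(fit, levene_center = c("median", "mean")) {
  stopifnot(inherits(fit, "hcc_anova"))
  levene_center <- match.arg(levene_center)
  r <- fit$residuals
  n <- length(r)

  flags <- character(0)
  if (n >= 3 && n <= 5000) {
    sw <- shapiro.test(r)
    shapiro <- list(statistic = unname(sw$statistic), p = sw$p.value)
    if (sw$p.value < 0.05) flags <- c(flags, "residuals non-normal (p < 0.05)")
  } else {
    shapiro <- list(statistic = NA_real_, p = NA_real_)
    flags <- c(flags, "normality test unavailable (n outside [3, 5000])")
  }

  cell <- interaction(fit$data$farm, fit$data$batch, drop = TRUE)
  center <- tapply(r, cell, if (levene_center == "median") median else mean)
  z <- abs(r - center[cell])
  df_lev <- c(nlevels(cell) - 1L, n - nlevels(cell))
  if (diff(range(z)) < 1e-10 * max(1, max(abs(r)))) {
    # no dispersion differences at all (constant |deviation|): statistic 0
    levene <- list(statistic = 0, df = df_lev, p = 1)
  } else {
    lev <- anova(lm(z ~ cell))
    levene <- list(statistic = lev[["F value"]][1],
                   df = unname(lev[["Df"]]), p = lev[["Pr(>F)"]][1])
  }
  if (is.finite(levene$p) && levene$p < 0.05) {
    flags <- c(flags, "heteroscedastic cells (Levene p < 0.05)")
  }

  qq <- qqnorm(r, plot.it = FALSE)
  structure(list(shapiro = shapiro, levene = levene,
                 qq = data.frame(theoretical = qq$x, sample = qq$y),
                 flags = flags),
            class = "hcc_diagnostics")
}

#' Tukey--Kramer comparison of the two batches within each farm
#'
#' The comparison family is, by default, all pairs of the (farm, batch) cell
#' means (the studentized-range family of the full interaction model, 40
#' cells in the reference design); from it the within-farm batch-1 vs
#' batch-2 contrasts are reported. `family = "within_farm"` restricts each
#' comparison to its own two cells (equivalent to an unadjusted t-test via
#' the q = t * sqrt(2) identity).
#'
#' @param cohort an `hcc_cohort` with exactly 2 batch labels.
#' @param family `"all_cells"` (default) or `"within_farm"`.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame of class `hcc_tukey`, one row per farm: `mean_diff`
#'   (batch2 - batch1, pg/mg), `adjusted_p`, `cohens_d_abs` (combined-sample
#'   denominator), `significant`.
#' @export
tukey_batch_comparisons <- function(cohort, family = c("all_cells",
                                                       "within_farm"),
                                    alpha = 0.05) {
  family <- match.arg(family)
  stopifnot(inherits(cohort, "hcc_cohort"))
  batches <- attr(cohort, "batch_ids")
  if (length(batches) != 2) stop("batch comparisons need exactly 2 batches")
  fit <- fit_two_way_anova(cohort)
  mse <- fit$table$mean_sq[fit$table$term == "residuals"]
  df_res <- fit$table$df[fit$table$term == "residuals"]
  sm <- batch_summaries(cohort)
  n_means <- if (family == "all_cells") nrow(sm) else 2L

  farms <- attr(cohort, "farm_ids")
  out <- lapply(farms, function(f) {
    s1 <- sm[sm$farm_id == f & sm$batch_id == batches[1], ]
    s2 <- sm[sm$farm_id == f & sm$batch_id == batches[2], ]
    diff <- s2$mean - s1$mean
    se <- sqrt(mse / 2 * (1 / s1$n + 1 / s2$n))  # Tukey-Kramer unequal n
    q <- abs(diff) / se
    p <- ptukey(q, nmeans = n_means, df = df_res, lower.tail = FALSE)
    d <- cohens_d_combined(s1$mean, s1$sd, s1$n, s2$mean, s2$sd, s2$n)
    data.frame(farm_id = f, mean_diff = diff, adjusted_p = p,
               cohens_d_abs = d, significant = p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("hcc_tukey", "data.frame")
  out
}

#' Cohen's d from two batch summaries, combined-sample denominator
#'
#' Absolute difference of the two means divided by the SD of the combined
#' two-batch sample reconstructed from summary statistics: with combined mean
#' `m = (n1 m1 + n2 m2) / (n1 + n2)`, the combined variance is
#' `[n1 (s1^2 + (m1 - m)^2) + n2 (s2^2 + (m2 - m)^2)] / (n1 + n2)`. The
#' denominator therefore includes the between-batch spread; a pooled
#' within-batch SD is deliberately not used, as it describes a different
#' (larger) standardized difference.
#'
#' @param m1,s1,n1 mean, sample SD and size of batch 1.
#' @param m2,s2,n2 mean, sample SD and size of batch 2.
#' @return non-negative scalar; `Inf` with a warning when both batches are
#'   degenerate (zero combined variance) yet the means differ.
#' @export
cohens_d_combined <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(s1 >= 0, s2 >= 0, n1 >= 2, n2 >= 2)
  if (m1 == m2 && s1 == 0 && s2 == 0) return(0)
  m <- (n1 * m1 + n2 * m2) / (n1 + n2)
  v <- (n1 * (s1^2 + (m1 - m)^2) + n2 * (s2^2 + (m2 - m)^2)) / (n1 + n2)
  if (v == 0) {
    warning("zero combined variance with unequal means: d is infinite")
    return(Inf)
  }
  abs(m1 - m2) / sqrt(v)
}

#' Regression of batch SD on batch mean
#'
#' Across batches, HCC dispersion grows with the batch mean; this returns the
#' Pearson correlation (two-sided test) and the OLS line of SD against mean.
#'
#' @param summaries an [batch_summaries()] data.frame (>= 3 batches).
#' @return list: `pearson_r`, `p`, `slope`, `intercept`, `n_batches`.
#' @export
mean_sd_regression <- function(summaries) {
  stopifnot(is.data.frame(summaries), all(c("mean", "sd") %in%
                                            names(summaries)))
  if (nrow(summaries) < 3) stop("need at least 3 batches")
  if (var(summaries$mean) == 0) stop("zero variance in batch means: r undefined")
  ct <- cor.test(summaries$mean, summaries$sd, method = "pearson")
  co <- coef(lm(sd ~ mean, data = summaries))
  list(pearson_r = unname(ct$estimate), p = ct$p.value,
       slope = unname(co[2]), intercept = unname(co[1]),
       n_batches = nrow(summaries))
}
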