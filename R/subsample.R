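# Subsample study ------------------------------------------------------------
#
# How well do j pigs characterize a batch of n? For every batch, every
# j-subset (exhaustively when C(n, j) is tractable, seeded Monte Carlo
# otherwise) is scored by the relative difference of its mean (delta) and of
# its sample SD (delta') from the full batch. Per-batch 5th/50th/95th
# percentiles of those distributions, and their means across batches, are
# the study's deliverable. All relative differences are fractions; multiply
# by 100 for percent.

#' Configuration of the subsample study
#'
#' @param sizes subsample sizes j to evaluate (default the classic
#'   5/10/15/20 out of a 24-pig batch).
#' @param mode `"exact"` (exhaustive enumeration, falling back to Monte
#'   Carlo with a notice when `C(n, j)` exceeds `max_enumeration`) or
#'   `"monte_carlo"`.
#' @param max_enumeration largest subset count enumerated exactly; the
#'   default 2e6 keeps every size of a 24-pig batch exact (max C(24, 10) =
#'   1,961,256) while bounding runtime.
#' @param n_draws Monte Carlo draws per (batch, j).
#' @param seed integer seed for Monte Carlo draws.
#' @param percentiles summary percentiles (default 5, 50, 95).
#' @return validated list of class `hcc_subsample_config`.
#' @export
subsample_config <- function(sizes = c(5L, 10L, 15L, 20L),
                             mode = c("exact", "monte_carlo"),
                             max_enumeration = 2e6, n_draws = 10000L,
                             seed = 1L, percentiles = c(5, 50, 95)) {
  mode <- match.arg(mode)
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 2)) stop("subsample sizes must be >= 2")
  if (mode == "monte_carlo" && n_draws < 1) stop("n_draws must be >= 1")
  if (any(percentiles < 0 | percentiles > 100)) {
    stop("percentiles must lie in [0, 100]")
  }
  structure(list(sizes = sizes, mode = mode,
                 max_enumeration = max_enumeration,
                 n_draws = as.integer(n_draws), seed = as.integer(seed),
                 percentiles = sort(percentiles)),
            class = "hcc_subsample_config")
}

#' Enumerate all j-subsets of 1..n in lexicographic order
#'
#' Thin, validated wrapper used for small designs and as the reference
#' route in tests; the exhaustive scoring path streams the same
#' lexicographic order in compiled code without materializing the subsets.
#'
#' @param n,j set and subset sizes, `1 <= j <= n`.
#' @return integer matrix, `choose(n, j)` rows of j sorted indices.
#' @export
enumerate_subsets <- function(n, j) {
  n <- as.integer(n); j <- as.integer(j)
  if (j < 1 || j > n) stop("j must lie in [1, n]")
  if (choose(n, j) > 2e6) stop("too many subsets to materialize; ",
                               "use the streaming exact mode")
  t(combn(n, j))
}

#' Relative differences of all (or sampled) subsamples of one batch
#'
#' For each subsample i of size j: `delta = (mean_i - mean_n) / mean_n` and
#' `delta_prime = (sd_i - sd_n) / sd_n`, with sample SDs (denominator j - 1
#' for the subsample, n - 1 for the batch). Exact mode enumerates every
#' subset when `C(n, j) <= max_enumeration`, otherwise falls back to seeded
#' Monte Carlo with a notice.
#'
#' @param values numeric vector of one batch's HCC values (length n >= j).
#' @param j subsample size.
#' @param config an [subsample_config()].
#' @param seed RNG seed for Monte Carlo (default taken from `config`).
#' @return numeric matrix, columns `delta` and `delta_prime` (fractions);
#'   attributes `mode` ("exact" or "monte_carlo") and `n_subsamples`.
#' @export
relative_differences <- function(values, j, config = subsample_config(),
                                 seed = config$seed) {
  n <- length(values)
  j <- as.integer(j)
  if (j < 2 || j > n) stop("j must lie in [2, n]")
  if (sd(values) == 0) stop("zero batch SD: delta' undefined")
  n_subsets <- choose(n, j)
  exact <- config$mode == "exact" && n_subsets <= config$max_enumeration
  if (config$mode == "exact" && !exact) {
    message("C(", n, ", ", j, ") = ", format(n_subsets, big.mark = ","),
            " exceeds max_enumeration; falling back to Monte Carlo (",
            config$n_draws, " draws)")
  }
  if (exact) {
    out <- rel_diff_exact_cpp(as.numeric(values), j)
  } else {
    old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           .GlobalEnv))
    set.seed(seed)
    mu <- mean(values)
    sigma <- sd(values)
    draws <- vapply(seq_len(config$n_draws),
                    function(i) values[sample.int(n, j)],
                    numeric(j))
    m <- colMeans(draws)
    s <- sqrt((colSums(draws^2) - j * m^2) / (j - 1))
    out <- cbind((m - mu) / mu, (s - sigma) / sigma)
  }
  colnames(out) <- c("delta", "delta_prime")
  attr(out, "mode") <- if (exact) "exact" else "monte_carlo"
  attr(out, "n_subsamples") <- nrow(out)
  out
}

#' Percentile summary of one batch's relative-difference distribution
#'
#' Percentiles use the linear-interpolation convention between order
#' statistics (`stats::quantile` type 7).
#'
#' @param rd matrix from [relative_differences()].
#' @param percentiles percentile levels in [0, 100].
#' @return data.frame: `statistic` (delta / delta_prime), `percentile`,
#'   `value` (fraction).
#' @export
percentile_summary <- function(rd, percentiles = c(5, 50, 95)) {
  if (is.null(dim(rd)) || nrow(rd) == 0) stop("empty relative-difference set")
  probs <- percentiles / 100
  out <- rbind(
    data.frame(statistic = "delta", percentile = percentiles,
               value = unname(quantile(rd[, "delta"], probs, type = 7))),
    data.frame(statistic = "delta_prime", percentile = percentiles,
               value = unname(quantile(rd[, "delta_prime"], probs, type = 7))))
  rownames(out) <- NULL
  out
}

#' Run the subsample study over every batch of a cohort
#'
#' Every (farm, batch) cell is treated as an independent initial sample.
#' Batches smaller than a requested j skip that size with a notice. Monte
#' Carlo seeds are fanned out deterministically from `config$seed` per
#' (batch, j), so results are reproducible and draws differ across cells.
#'
#' @param cohort an `hcc_cohort`.
#' @param config an [subsample_config()].
#' @return list of class `hcc_subsample`: `per_batch` (long data.frame:
#'   farm_id, batch_id, n_batch, j, n_subsamples, mode, statistic,
#'   percentile, value) and `means` (mean of each percentile across batches
#'   per j and statistic), both in fractions; `config`.
#' @export
run_subsample_study <- function(cohort, config = subsample_config()) {
  stopifnot(inherits(cohort, "hcc_cohort"))
  cells <- split(cohort$hcc,
                 list(farm = cohort$farm_id, batch = cohort$batch_id),
                 drop = TRUE, sep = "\r")
  keys <- strsplit(names(cells), "\r", fixed = TRUE)
  ord <- order(vapply(keys, `[`, "", 1L), vapply(keys, `[`, "", 2L))
  per_batch <- list()
  counter <- 0L
  for (ci in ord) {
    vals <- cells[[ci]]
    farm <- keys[[ci]][1]
    batch <- keys[[ci]][2]
    for (j in config$sizes) {
      counter <- counter + 1L
      if (j > length(vals)) {
        message("batch (", farm, ", ", batch, ") has n = ", length(vals),
                " < j = ", j, "; size skipped")
        next
      }
      rd <- relative_differences(vals, j, config,
                                 seed = (config$seed + counter) %% 2147483647)
      ps <- percentile_summary(rd, config$percentiles)
      per_batch[[length(per_batch) + 1L]] <-
        cbind(data.frame(farm_id = farm, batch_id = batch,
                         n_batch = length(vals), j = j,
                         n_subsamples = attr(rd, "n_subsamples"),
                         mode = attr(rd, "mode"), stringsAsFactors = FALSE),
              ps)
    }
  }
  per_batch <- do.call(rbind, per_batch)
  means <- aggregate(value ~ j + statistic + percentile, data = per_batch,
                     FUN = mean)
  means <- means[order(means$statistic, means$j, means$percentile), ]
  rownames(means) <- NULL
  structure(list(per_batch = per_batch, means = means, config = config),
            class = "hcc_subsample")
}

#' @export
print.hcc_subsample <- function(x, ...) {
  cat("Subsample study: ", length(unique(paste(x$per_batch$farm_id,
                                               x$per_batch$batch_id))),
      " batches, sizes {", paste(x$config$sizes, collapse = ", "), "}\n",
      sep = "")
  m <- x$means
  m$value_pct <- 100 * m$value
  print(format(m, digits = 3), row.names = FALSE)
  invisible(x)
}
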