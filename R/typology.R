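# Farm typology --------------------------------------------------------------
#
# Farms are profiled by four active variables -- the per-farm batch means and
# batch SDs of HCC -- standardized and decomposed by PCA; Ward hierarchical
# clustering on the component scores partitions the farms; clusters are then
# characterized by v.test statistics on active and supplementary variables.
# Conventions follow the standard HCPC practice: population scaling
# (denominator N) for both standardization and the quantitative v.test.

#' Build the active matrix of per-farm batch statistics
#'
#' @param summaries an [batch_summaries()] data.frame in which every farm has
#'   exactly two batches.
#' @return numeric matrix (farms x 4), rows sorted by farm id, columns
#'   `mean_batch1`, `mean_batch2`, `sd_batch1`, `sd_batch2` where "batch1" is
#'   the lexicographically first batch label.
#' @export
build_active_matrix <- function(summaries) {
  stopifnot(is.data.frame(summaries),
            all(c("farm_id", "batch_id", "mean", "sd") %in% names(summaries)))
  farms <- sort(unique(summaries$farm_id))
  batches <- sort(unique(summaries$batch_id))
  if (length(batches) != 2) {
    stop("active matrix needs exactly 2 batch labels, got ", length(batches))
  }
  counts <- table(summaries$farm_id)
  bad <- names(counts)[counts != 2L]
  if (length(bad) > 0) {
    stop("farm(s) without exactly 2 batches: ", paste(bad, collapse = ", "))
  }
  s <- summaries[order(summaries$farm_id, summaries$batch_id), ]
  b1 <- s[s$batch_id == batches[1], ]
  b2 <- s[s$batch_id == batches[2], ]
  m <- cbind(mean_batch1 = b1$mean, mean_batch2 = b2$mean,
             sd_batch1 = b1$sd, sd_batch2 = b2$sd)
  rownames(m) <- farms
  m
}

#' Standardized PCA of the active matrix
#'
#' Columns are centered and scaled to unit population variance (denominator
#' N); the eigendecomposition is that of the correlation matrix. Component
#' signs are fixed by making the largest-magnitude loading of each component
#' positive, so results are reproducible across platforms.
#'
#' @param x active matrix (>= 3 rows, no zero-variance column).
#' @return list of class `hcc_pca`: `eigenvalues`, `variance_explained`
#'   (fractions summing to 1), `loadings` (variable x component), `scores`
#'   (farm x component), `center`, `scale`.
#' @export
standardized_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("PCA needs at least 3 farms")
  ctr <- colMeans(x)
  scl <- sqrt(colMeans(sweep(x, 2, ctr)^2))  # population SD
  zero <- which(scl == 0)
  if (length(zero) > 0) {
    stop("zero-variance column: ", colnames(x)[zero[1]])
  }
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  cmat <- crossprod(z) / nrow(z)            # correlation matrix
  e <- eigen(cmat, symmetric = TRUE)
  vec <- e$vectors
  for (j in seq_len(ncol(vec))) {           # deterministic sign convention
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  dimnames(vec) <- list(colnames(x), paste0("PC", seq_len(ncol(vec))))
  scores <- z %*% vec
  structure(list(eigenvalues = pmax(e$values, 0),
                 variance_explained = pmax(e$values, 0) / ncol(x),
                 loadings = vec, scores = scores,
                 center = ctr, scale = scl),
            class = "hcc_pca")
}

#' Ward hierarchical clustering on principal-component scores
#'
#' Agglomerative clustering (Ward criterion, `hclust` method `ward.D2` on
#' Euclidean distances) of the farms in the space of all retained component
#' scores. With `k = "auto"` the tree is cut where the relative gain in
#' between-cluster inertia is largest (the biggest jump in merge heights).
#' An optional k-means consolidation step (deterministic: Lloyd iterations
#' started from the hierarchical cluster centroids) is OFF by default.
#'
#' @param pca an `hcc_pca`.
#' @param k integer number of clusters, or `"auto"`.
#' @param n_components how many leading components to cluster on (default:
#'   all).
#' @param consolidate run the k-means refinement step.
#' @return named integer vector of cluster labels (1..k), names = farm ids,
#'   clusters numbered by first occurrence in sorted farm order; attribute
#'   `hclust` holds the tree.
#' @export
ward_hcpc <- function(pca, k = "auto", n_components = NULL,
                      consolidate = FALSE) {
  stopifnot(inherits(pca, "hcc_pca"))
  sc <- pca$scores
  if (!is.null(n_components)) sc <- sc[, seq_len(n_components), drop = FALSE]
  n <- nrow(sc)
  hc <- stats::hclust(stats::dist(sc), method = "ward.D2")
  if (identical(k, "auto")) {
    h <- rev(hc$height)                     # heights of the last merges
    kmax <- min(10L, n - 1L)
    ratios <- h[seq_len(kmax - 1L)] / h[seq_len(kmax - 1L) + 1L]
    k <- which.max(ratios) + 1L
  }
  k <- as.integer(k)
  if (k < 1 || k > n) stop("k must be between 1 and the number of farms (", n,
                           ")")
  labels <- stats::cutree(hc, k = k)
  if (consolidate && k < n) {
    centers <- do.call(rbind, lapply(split(as.data.frame(sc), labels),
                                     colMeans))
    km <- stats::kmeans(sc, centers = centers, algorithm = "Lloyd",
                        iter.max = 100L)
    labels <- setNames(km$cluster, rownames(sc))
  }
  ord <- order(names(labels))
  relabel <- setNames(seq_len(k), unique(labels[ord]))
  labels <- setNames(as.integer(relabel[as.character(labels)]), names(labels))
  attr(labels, "hclust") <- hc
  labels
}

#' v.test of a quantitative variable for each cluster
#'
#' For cluster k of size `n_k` among `N` farms,
#' `v = (xbar_k - xbar) / sqrt((s^2 / n_k) * (N - n_k) / (N - 1))`
#' with `xbar` the overall mean and `s^2` the population variance
#' (denominator N) of the variable. Under a random partition v is
#' approximately standard normal; `|v| >= 1.96` flags a cluster whose mean
#' departs from the cohort at the 5% level.
#'
#' @param values named numeric vector (names = farm ids).
#' @param labels named integer cluster labels over the same farms.
#' @return data.frame: `cluster`, `n`, `cluster_mean`, `overall_mean`, `v`,
#'   `p` (two-sided normal).
#' @export
vtest_quantitative <- function(values, labels) {
  stopifnot(!is.null(names(values)), !is.null(names(labels)))
  values <- values[names(labels)]
  if (anyNA(values)) stop("values missing for some labelled farms")
  N <- length(values)
  s2 <- mean((values - mean(values))^2)     # population variance
  out <- lapply(sort(unique(labels)), function(kk) {
    idx <- labels == kk
    nk <- sum(idx)
    if (nk == N) stop("cluster ", kk, " contains every farm: v undefined")
    se <- sqrt(s2 / nk * (N - nk) / (N - 1))
    v <- if (se == 0) 0 else (mean(values[idx]) - mean(values)) / se
    data.frame(cluster = kk, n = nk, cluster_mean = mean(values[idx]),
               overall_mean = mean(values), v = v,
               p = 2 * pnorm(-abs(v)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' v.test of a categorical variable for each (level, cluster) pair
#'
#' The in-cluster count of a level is referred to its hypergeometric
#' distribution given the overall count. The reported p-value is the smaller
#' tail probability, `P(X >= x)` or `P(X <= x)`; the v.test is the signed
#' normal quantile `sign * qnorm(1 - p / 2)`, positive when the level is
#' over-represented in the cluster. This is the convention used by standard
#' cluster-description tooling and is what published v values for management
#' practices correspond to.
#'
#' @param flags named character vector of levels (names = farm ids); NA
#'   farms are dropped for that variable.
#' @param labels named integer cluster labels.
#' @return data.frame: `level`, `cluster`, `n_cluster`, `count_in_cluster`,
#'   `count_overall`, `v`, `p`.
#' @export
vtest_categorical <- function(flags, labels) {
  stopifnot(!is.null(names(flags)), !is.null(names(labels)))
  flags <- flags[names(labels)]
  keep <- !is.na(flags)
  flags <- flags[keep]
  labs <- labels[keep]
  N <- length(flags)
  levels_ <- sort(unique(flags))
  out <- list()
  for (lv in levels_) {
    K <- sum(flags == lv)
    for (kk in sort(unique(labs))) {
      nk <- sum(labs == kk)
      x <- sum(flags == lv & labs == kk)
      p_ge <- phyper(x - 1, K, N - K, nk, lower.tail = FALSE)
      p_le <- phyper(x, K, N - K, nk)
      p <- min(1, p_ge, p_le)
      s <- sign(x / nk - K / N)
      v <- s * qnorm(1 - p / 2)
      out[[length(out) + 1L]] <-
        data.frame(level = lv, cluster = kk, n_cluster = nk,
                   count_in_cluster = x, count_overall = K, v = v, p = p,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Full farm typology: PCA + Ward clustering + cluster characterization
#'
#' Convenience wrapper chaining [build_active_matrix()],
#' [standardized_pca()], [ward_hcpc()] and the v.tests of the four active
#' variables; supplementary metadata variables, when given, are characterized
#' by [vtest_categorical()].
#'
#' @param summaries an [batch_summaries()] data.frame.
#' @param metadata optional `hcc_farm_metadata`.
#' @param k clusters ("auto" or integer; field-study mode uses 3).
#' @param consolidate forwarded to [ward_hcpc()].
#' @param alpha significance threshold used to mark reported v values.
#' @return list of class `hcc_typology`: `active`, `pca`, `labels`,
#'   `vtest_active` (long data.frame with `variable` column),
#'   `vtest_supplementary` (or NULL).
#' @export
farm_typology <- function(summaries, metadata = NULL, k = "auto",
                          consolidate = FALSE, alpha = 0.05) {
  active <- build_active_matrix(summaries)
  pca <- standardized_pca(active)
  labels <- ward_hcpc(pca, k = k, consolidate = consolidate)
  va <- do.call(rbind, lapply(colnames(active), function(vn) {
    res <- vtest_quantitative(setNames(active[, vn], rownames(active)), labels)
    cbind(variable = vn, res, stringsAsFactors = FALSE)
  }))
  va$significant <- va$p < alpha
  vs <- NULL
  if (!is.null(metadata)) {
    vars <- intersect(names(farm_metadata_dictionary()), names(metadata))
    vs <- do.call(rbind, lapply(vars, function(vn) {
      fl <- setNames(as.character(metadata[[vn]]), metadata$farm_id)
      res <- vtest_categorical(fl, labels)
      cbind(variable = vn, res, stringsAsFactors = FALSE)
    }))
    if (!is.null(vs)) vs$significant <- vs$p < alpha
  }
  structure(list(active = active, pca = pca, labels = labels,
                 vtest_active = va, vtest_supplementary = vs),
            class = "hcc_typology")
}

#' @export
print.hcc_typology <- function(x, ...) {
  k <- length(unique(x$labels))
  cat("Farm typology: ", nrow(x$active), " farms, ", k, " clusters\n", sep = "")
  cat("PCA variance explained (%): ",
      paste(format(100 * x$pca$variance_explained, digits = 3),
            collapse = ", "), "\n", sep = "")
  for (kk in sort(unique(x$labels))) {
    cat("  cluster ", kk, ": ",
        paste(names(x$labels)[x$labels == kk], collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}
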