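# Independent oracles: brute-force routes kept deliberately separate from
# the implementation paths they check.

# Sequential SS by direct projection onto nested group-mean spaces. Valid on
# balanced designs, where sequential and marginal SS coincide: each term's
# SS is computed from group means alone, never via lm/anova.
oracle_ss_balanced <- function(df) {
  y <- df$hcc
  g <- mean(y)
  batch_means <- tapply(y, df$batch_id, mean)[df$batch_id]
  farm_means <- tapply(y, df$farm_id, mean)[df$farm_id]
  cell <- paste(df$farm_id, df$batch_id)
  cell_means <- tapply(y, cell, mean)[cell]
  c(batch = sum((batch_means - g)^2),
    farm = sum((farm_means - g)^2),
    interaction = sum((cell_means - farm_means - batch_means + g)^2),
    residuals = sum((y - cell_means)^2),
    total = sum((y - g)^2))
}

# Eigenvalues of a symmetric matrix by power iteration with deflation.
oracle_power_eigen <- function(m, n_iter = 5000) {
  k <- ncol(m)
  vals <- numeric(k)
  for (i in seq_len(k)) {
    v <- rep(1 / sqrt(k), k)
    for (it in seq_len(n_iter)) {
      w <- m %*% v
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) break
      v <- as.numeric(w / nw)
    }
    lambda <- as.numeric(t(v) %*% m %*% v)
    vals[i] <- lambda
    m <- m - lambda * tcrossprod(v)
  }
  sort(vals, decreasing = TRUE)
}

# Hypergeometric upper/lower tail by direct summation of choose() products.
oracle_hyper_tails <- function(N, K, nk, x) {
  pmf <- function(i) choose(K, i) * choose(N - K, nk - i) / choose(N, nk)
  support <- max(0, nk - (N - K)):min(K, nk)
  list(p_ge = sum(vapply(support[support >= x], pmf, 0)),
       p_le = sum(vapply(support[support <= x], pmf, 0)))
}

# Pearson r straight from the covariance/variance definition.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# All-subset relative differences via utils::combn (materialized route,
# independent of the streaming C++ enumeration).
oracle_rel_diffs <- function(values, j) {
  mu <- mean(values)
  sigma <- sd(values)
  sets <- combn(length(values), j)
  t(apply(sets, 2, function(idx) {
    c(delta = (mean(values[idx]) - mu) / mu,
      delta_prime = (sd(values[idx]) - sigma) / sigma)
  }))
}
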