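test_that("active matrix is deterministic and order-invariant", {
  sm <- batch_summaries(toy_cohort())
  m <- build_active_matrix(sm)
  expect_equal(dim(m), c(2, 4))
  expect_equal(colnames(m), c("mean_batch1", "mean_batch2",
                              "sd_batch1", "sd_batch2"))
  expect_equal(unname(m["A", ]),
               c(mean(c(10, 12)), mean(c(20, 26)), sd(c(10, 12)),
                 sd(c(20, 26))))
  expect_equal(build_active_matrix(sm[sample.int(nrow(sm)), ]), m)

  t2 <- reference_summaries()
  m2 <- build_active_matrix(t2)
  expect_equal(dim(m2), c(20, 4))
  expect_equal(unname(m2["A", ]), c(4.9, 13.7, 1.6, 6.1))

  bad <- sm[-1, ]
  expect_error(build_active_matrix(bad), "A")
})

test_that("standardized PCA has the closed-form 2x2 eigenstructure", {
  set.seed(2)
  x1 <- rnorm(12)
  x <- cbind(a = x1, b = 2 * x1 + 1, c = rnorm(12))
  # columns a and b perfectly correlated: r(a,b) = 1
  p <- standardized_pca(x[, c("a", "b")])
  expect_equal(p$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_equal(sum(p$variance_explained), 1)
  expect_equal(unname(colMeans(p$scores)), c(0, 0), tolerance = 1e-12)
  expect_error(standardized_pca(cbind(x, d = 1)), "zero-variance column: d")
})

test_that("PCA eigenvalues match a power-iteration oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    x <- matrix(rnorm(20), 5, 4)
    p <- standardized_pca(x)
    z <- scale(x) * sqrt(5 / 4)  # population scaling
    oracle <- oracle_power_eigen(crossprod(z) / 5)
    expect_equal(p$eigenvalues, oracle, tolerance = 1e-8)
  }
})

test_that("Ward clustering: singletons, separable blobs, determinism", {
  t2 <- reference_summaries()
  pca <- standardized_pca(build_active_matrix(t2))
  lab_all <- ward_hcpc(pca, k = 20)
  expect_equal(as.integer(table(lab_all)), rep(1L, 20))
  expect_error(ward_hcpc(pca, k = 21), "between 1")

  # two well-separated Gaussian blobs are recovered exactly at k = 2
  set.seed(9)
  blob <- rbind(matrix(rnorm(24, 0, 0.3), 8, 3),
                matrix(rnorm(21, 10, 0.3), 7, 3))
  rownames(blob) <- sprintf("F%02d", 1:15)
  colnames(blob) <- c("v1", "v2", "v3")
  blob <- cbind(blob, v4 = rnorm(15))
  labs <- ward_hcpc(standardized_pca(blob), k = 2)
  expect_equal(unname(labs[1:8]), rep(1L, 8))
  expect_equal(unname(labs[9:15]), rep(2L, 7))
  # auto-k picks the two blobs as well
  expect_equal(ward_hcpc(standardized_pca(blob), k = "auto"), labs)

  # labels invariant to farm input order
  perm <- sample.int(20)
  pca_p <- standardized_pca(build_active_matrix(t2)[perm, ])
  expect_equal(ward_hcpc(pca_p, k = 3)[sort(rownames(pca$scores))],
               ward_hcpc(pca, k = 3)[sort(rownames(pca$scores))])
})

test_that("quantitative v.test: zero at no contrast, affine invariance", {
  vals <- setNames(c(1, 2, 3, 4, 5, 6), paste0("F", 1:6))
  labs <- setNames(c(1L, 2L, 1L, 2L, 1L, 2L), paste0("F", 1:6))
  # cluster mean equal to overall mean -> v exactly 0
  v0 <- vtest_quantitative(setNames(c(2, 8, 5), c("a", "b", "c")),
                           setNames(c(1L, 1L, 2L), c("a", "b", "c")))
  expect_equal(v0$v[v0$cluster == 1], 0)  # cluster mean 5 == overall mean 5

  r1 <- vtest_quantitative(vals, labs)
  r2 <- vtest_quantitative(3 * vals - 10, labs)
  expect_equal(r1$v, r2$v, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_error(vtest_quantitative(vals, setNames(rep(1L, 6), names(vals))),
               "every farm")
})

test_that("v.test is approximately standard normal under random partitions", {
  set.seed(14)
  vals <- setNames(rnorm(40), sprintf("F%02d", 1:40))
  draws <- vapply(1:2000, function(i) {
    labs <- setNames(rep(2L, 40), names(vals))
    labs[sample.int(40, 8)] <- 1L
    vtest_quantitative(vals, labs)$v[1]
  }, numeric(1))
  ks <- suppressWarnings(ks.test(draws, pnorm))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("categorical v.test matches the hypergeometric-summation oracle", {
  farms <- sprintf("F%02d", 1:20)
  labs <- setNames(rep(c(1L, 2L), c(3, 17)), farms)

  # ubiquitous level carries no information
  flags <- setNames(rep("yes", 20), farms)
  r <- vtest_categorical(flags, labs)
  expect_equal(r$v, c(0, 0))
  expect_equal(r$p, c(1, 1))

  # level with overall count 3 fully inside the 3-farm cluster
  flags3 <- setNames(rep(c("no", "yes"), c(3, 17)), farms)
  r3 <- vtest_categorical(flags3, labs)
  tails <- oracle_hyper_tails(20, 3, 3, 3)
  row <- r3[r3$level == "no" & r3$cluster == 1, ]
  expect_equal(row$p, tails$p_ge, tolerance = 1e-12)
  expect_equal(row$v, qnorm(1 - tails$p_ge / 2), tolerance = 1e-12)

  # overall count 2 fully inside the 3-farm cluster: the published-table
  # pattern for the organic-practice modalities, v = 2.41
  flags2 <- setNames(rep(c("no", "yes"), c(2, 18)), farms)
  r2 <- vtest_categorical(flags2, labs)
  row2 <- r2[r2$level == "no" & r2$cluster == 1, ]
  expect_equal(row2$v, 2.41, tolerance = 0.005)

  # under-representation: a level held by 17 farms with only one of them in
  # the 3-farm cluster, v = -1.99
  flags17 <- setNames(rep("no", 20), farms)
  flags17[c("F02", "F03", "F10")] <- "yes"   # 17 "no" overall, 1 in cluster
  r17 <- vtest_categorical(flags17, labs)
  row17 <- r17[r17$level == "no" & r17$cluster == 1, ]
  tails17 <- oracle_hyper_tails(20, 17, 3, 1)
  expect_equal(row17$p, tails17$p_le, tolerance = 1e-12)
  expect_equal(row17$v, -1.99, tolerance = 0.005)
})

test_that("full typology wrapper ties the stages together", {
  t2 <- reference_summaries()
  typ <- farm_typology(t2, k = 3)
  expect_equal(sort(unique(unname(typ$labels))), 1:3)
  expect_equal(names(which(typ$labels == typ$labels[["A"]])),
               c("A", "B", "G"))
  va <- typ$vtest_active
  expect_equal(nrow(va), 12)  # 4 variables x 3 clusters
  expect_true(all(c("variable", "cluster", "v", "p") %in% names(va)))
})
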