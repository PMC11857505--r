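test_that("the five scalings match their closed forms", {
  m <- bin_matrix(matrix(c(2, 4, 6, 2, 3, 100), nrow = 3,
                         dimnames = list(NULL, c("b1", "b2"))),
                  labels = c("OA", "OA", "RA"))
  mm <- normalize_bins(m, "minmax")
  expect_equal(mm$values[, 1], c(0, 0.5, 1), ignore_attr = TRUE)

  z <- normalize_bins(m, "zscore")
  expect_equal(colMeans(z$values), c(0, 0), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(apply(z$values, 2, sd), c(1, 1), tolerance = 1e-9,
               ignore_attr = TRUE)

  ma <- normalize_bins(m, "maxabs")
  expect_equal(ma$values[, 2], c(2, 3, 100) / 100, ignore_attr = TRUE)

  x <- c(1, 2, 3, 4, 100)
  m5 <- bin_matrix(cbind(b = x), labels = c("OA", "OA", "OA", "RA", "RA"))
  mp <- normalize_bins(m5, "median_pareto")
  expect_equal(mp$values[, 1], (x - 3) / sqrt(sd(x)), ignore_attr = TRUE)
  rb <- normalize_bins(m5, "robust")
  expect_equal(rb$values[, 1], (x - 3) / (4 - 2), ignore_attr = TRUE)

  const <- bin_matrix(cbind(flat = rep(5, 4), ok = c(1, 2, 3, 4)),
                      labels = c("OA", "OA", "RA", "RA"))
  expect_error(normalize_bins(const, "zscore"), "flat")
  expect_error(normalize_bins(const, "minmax"), "flat")
})

test_that("minmax maps every bin onto [0,1] with the extremes attained", {
  sc <- screened_cohort(2)
  v <- sc$scaled$values
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(unname(apply(v, 2, min)), rep(0, ncol(v)))
  expect_equal(unname(apply(v, 2, max)), rep(1, ncol(v)))
})

test_that("pca_explore matches an eigendecomposition oracle", {
  set.seed(7)
  m <- bin_matrix(matrix(rnorm(24 * 40), 24), labels = rep(c("OA", "RA"),
                                                           c(10, 14)))
  res <- pca_explore(m, n_components = 10)
  ev <- eigen(cov(m$values), symmetric = TRUE)$values
  expect_equal(res$pc_variance, (ev / sum(ev))[1:10], tolerance = 1e-8)
  expect_true(all(diff(res$pc_variance) <= 1e-12))
  expect_lte(sum(res$pc_variance), 1 + 1e-9)
  # scores of distinct components are orthogonal
  g <- crossprod(res$scores)
  expect_equal(g[upper.tri(g)], rep(0, sum(upper.tri(g))), tolerance = 1e-6)

  rank1 <- bin_matrix(outer(c(1, 2, 3, 4), c(1, 5)) +
                        matrix(0, 4, 2, dimnames = list(NULL, c("a", "b"))),
                      labels = c("OA", "OA", "RA", "RA"))
  expect_equal(pca_explore(rank1, 1)$pc_variance, 1)
  expect_error(pca_explore(m, 25), "n_components")
})

test_that("silhouette agrees with the hand-computed a/b formula", {
  # two pairs of points; silhouette from explicit intra/inter distances
  vals <- matrix(c(0, 0, 1, 0, 10, 0, 11, 0), ncol = 2, byrow = TRUE)
  colnames(vals) <- c("f1", "f2")
  m <- bin_matrix(vals + 5, labels = c("OA", "OA", "RA", "RA"))
  s <- silhouette_by_label(m)
  a <- 1                       # intra-cluster distance for every point
  b <- c(mean(c(10, 11)), mean(c(9, 10)), mean(c(9, 10)), mean(c(10, 11)))
  expect_equal(s, mean((b - a) / pmax(a, b)), tolerance = 1e-12)
  expect_gt(s, 0.85)  # tight, far-apart groups approach 1

  one_member <- bin_matrix(vals, labels = c("OA", "RA", "RA", "RA"))
  expect_error(silhouette_by_label(one_member), "at least 2")
})

test_that("shuffled labels drive the silhouette to zero in expectation", {
  sc <- screened_cohort(2)
  set.seed(42)
  scores <- replicate(100, {
    silhouette_by_label(sc$scaled,
                        clusters = sample(as.integer(sc$scaled$labels)))
  })
  expect_lt(abs(mean(scores)), 0.05)
})

test_that("select_normalization maximizes the silhouette and is stable", {
  sc <- screened_cohort(2)
  rep1 <- select_normalization(sc$sim$matrix)
  expect_equal(rep1$silhouette, max(rep1$candidates$silhouette,
                                    na.rm = TRUE))
  expect_equal(rep1$method,
               rep1$candidates$method[which.max(rep1$candidates$silhouette)])
  # deterministic: re-running yields the identical report
  rep2 <- select_normalization(sc$sim$matrix)
  expect_identical(rep1$method, rep2$method)
  expect_identical(rep1$candidates, rep2$candidates)

  # invariant to column permutation of the input
  set.seed(1)
  perm <- sample(ncol(sc$sim$matrix$values))
  rep3 <- select_normalization(subset_bins(sc$sim$matrix, perm))
  expect_identical(rep1$method, rep3$method)
  expect_equal(rep1$silhouette, rep3$silhouette, tolerance = 1e-12)

  # a method whose precondition fails is skipped with a warning, not fatal
  vals <- cbind(spread = c(1, 2, 3, 4, 5), tied = c(7, 7, 7, 7, 100))
  m <- bin_matrix(vals, labels = c("OA", "OA", "OA", "RA", "RA"))
  expect_warning(rep4 <- select_normalization(m), "robust")
  expect_false(rep4$method == "robust")
})
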