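test_that("ensemble attributions equal exact enumeration Shapley values", {
  set.seed(15)
  labs <- rep(c("OA", "RA"), c(10, 14))
  y <- as.integer(labs == "RA")
  vals <- cbind(s1 = y + rnorm(24, sd = 0.6),
                s2 = -y + rnorm(24, sd = 0.8),
                n1 = rnorm(24), n2 = rnorm(24))
  m <- bin_matrix(vals, labels = labs)
  hp <- hyper_params(4, 30, 2, 2, 1, 4, "gini")
  model <- rf_fit(m, hp, seed = 2)
  got <- shapley_attribution(model, m)
  want <- brute_shapley(model, m$values)
  expect_equal(unname(got$shap_values), want$values, tolerance = 1e-6)
  expect_equal(got$base_value, want$base_value, tolerance = 1e-6)
})

test_that("local accuracy holds for every sample of a synthetic run", {
  sc <- screened_cohort(3)
  keep <- rfe_select(sc$rest, 50, sc$ranking)
  sub <- subset_bins(sc$rest, keep)
  hp <- hyper_params(50, 100, 6, 10, 6, "log2", "log_loss")
  model <- rf_fit(sub, hp, seed = 7)
  at <- shapley_attribution(model, sub)
  resid <- at$base_value + rowSums(at$shap_values) - at$prediction
  expect_lt(max(abs(resid)), 1e-6)
  expect_equal(at$prediction, unname(predict(model, sub)))
})

test_that("a constant-response model attributes nothing", {
  vals <- matrix(rnorm(24 * 3), 24,
                 dimnames = list(NULL, c("a", "b", "c")))
  m <- bin_matrix(vals, labels = rep(c("OA", "RA"), c(10, 14)))
  # min_split larger than n forbids any split: every tree is a root leaf
  hp <- hyper_params(3, 20, 3, 50, 1, 3, "gini")
  model <- rf_fit(m, hp, seed = 1)
  at <- shapley_attribution(model, m)
  expect_equal(unname(at$shap_values), matrix(0, 24, 3))
  expect_equal(unname(predict(model, m)), rep(at$base_value, 24))
})

test_that("duplicate features share their attribution symmetrically", {
  set.seed(6)
  labs <- rep(c("OA", "RA"), c(10, 14))
  x <- as.integer(labs == "RA") * 2 + rnorm(24, sd = 0.4)
  m <- bin_matrix(cbind(d1 = x, d2 = x), labels = labs)

  # symmetry axiom, exactly: a hand-built ensemble whose two trees use the
  # two duplicates interchangeably must attribute them identically
  leafy <- function(f) list(feature = c(f, -1L, -1L),
                            threshold = c(1, 0, 0),
                            left = c(1L, -1L, -1L), right = c(2L, -1L, -1L),
                            n = c(24, 10, 14), p1 = c(14 / 24, 0.1, 0.9),
                            feats = c(0L, 1L))
  model <- structure(list(trees = list(leafy(0L), leafy(1L)),
                          params = hyper_params(2, 2, 1, 2, 1, 2, "gini"),
                          bin_ids = c("d1", "d2")),
                     class = "rf_model")
  at <- shapley_attribution(model, m)
  expect_equal(at$shap_values[, "d1"], at$shap_values[, "d2"],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_lt(max(abs(at$base_value + rowSums(at$shap_values) -
                      at$prediction)), 1e-9)

  # a trained ensemble splits each tie by its per-tree feature order, so
  # the duplicates share the importance to within resampling noise
  trained <- rf_fit(m, hyper_params(2, 200, 2, 2, 1, 2, "entropy"),
                    seed = 3)
  mas <- colMeans(abs(shapley_attribution(trained, m)$shap_values))
  expect_gt(mas[["d1"]] / mas[["d2"]], 1 / 2)
  expect_lt(mas[["d1"]] / mas[["d2"]], 2)
})

test_that("rank_attributions orders by mean |shap| with directions", {
  sc <- screened_cohort(3)
  keep <- rfe_select(sc$rest, 30, sc$ranking)
  sub <- subset_bins(sc$rest, keep)
  hp <- hyper_params(30, 60, 6, 10, 6, "log2", "log_loss")
  model <- rf_fit(sub, hp, seed = 4)
  at <- shapley_attribution(model, sub)
  rk <- rank_attributions(at, k = 10)
  expect_equal(nrow(rk), 10)
  expect_true(all(diff(rk$mean_abs_shap) <= 1e-12))
  full <- rank_attributions(at, k = 30)
  expect_setequal(full$bin_id, sub$bins$bin_id)  # full ordering
  expect_error(rank_attributions(at, 31), "k must")

  # directions of top informative bins match the planted effect direction
  truth <- sc$sim$truth
  top_inf <- rk[grepl("informative", rk$bin_id), ]
  planted_dir <- truth$direction[match(top_inf$bin_id, truth$bin_id)]
  expect_gte(mean(top_inf$direction == planted_dir), 0.9)
})

test_that("a dominant planted signal ranks first", {
  set.seed(10)
  labs <- rep(c("OA", "RA"), c(10, 14))
  y <- as.integer(labs == "RA")
  vals <- cbind(strong = 3 * y + rnorm(24, sd = 0.3),
                weak = 0.3 * y + rnorm(24),
                noise = rnorm(24))
  m <- bin_matrix(vals, labels = labs)
  model <- rf_fit(m, hyper_params(3, 50, 4, 4, 2, 3, "gini"), seed = 5)
  rk <- rank_attributions(shapley_attribution(model, m), k = 3)
  expect_equal(rk$bin_id[1], "strong")
  expect_equal(rk$direction[1], "RA")
})

test_that("marker comparison computes overlaps, uniques and ambiguity", {
  mk_pls <- function(oa, ra) {
    list(ranking_OA = data.frame(metabolite_name = oa),
         ranking_RA = data.frame(metabolite_name = ra))
  }
  mk_ml <- function(oa, ra) {
    data.frame(metabolite_name = c(oa, ra),
               direction = rep(c("OA", "RA"), c(length(oa), length(ra))))
  }
  cmp <- compare_selections(mk_pls(c("glc", "gln"), c("pro")),
                            mk_ml(c("glc", "tau"), c("pro", "ace")))
  expect_equal(cmp$OA$both, "glc")
  expect_equal(cmp$OA$plsda_only, "gln")
  expect_equal(cmp$OA$ml_only, "tau")
  expect_equal(cmp$RA$both, "pro")
  expect_equal(cmp$RA$ml_only, "ace")
  expect_length(cmp$ambiguous, 0)

  # identical selections: all overlap, no uniques
  same <- compare_selections(mk_pls(c("a", "b"), c("c")),
                             mk_ml(c("a", "b"), c("c")))
  expect_equal(same$OA$both, c("a", "b"))
  expect_length(same$OA$plsda_only, 0)
  expect_length(same$OA$ml_only, 0)

  # a metabolite in one method's OA list and the other's RA list is
  # ambiguous, and the comparison is symmetric in the method labels
  amb <- compare_selections(mk_pls(c("lys"), c("x")), mk_ml(c("y"), c("lys")))
  expect_equal(amb$ambiguous, "lys")
  swapped <- compare_selections(mk_pls(c("y"), c("lys")),
                                mk_ml(c("lys"), c("x")))
  expect_equal(swapped$ambiguous, "lys")
})
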