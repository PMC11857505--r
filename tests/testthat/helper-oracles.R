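# Independent oracles and small fixtures used across the suite.

# Exhaustive decision-stump search: every midpoint threshold and both
# polarities, MCC computed from explicit prediction vectors. Written
# deliberately without any code shared with stump_mcc().
brute_stump <- function(values, labels) {
  y <- as.integer(labels == "RA")
  u <- sort(unique(values))
  best <- list(mcc = -2)
  if (length(u) < 2) return(list(mcc = 0))
  thr <- (head(u, -1) + tail(u, -1)) / 2
  for (t in thr) {
    for (pol in c("high_RA", "high_OA")) {
      pred <- if (pol == "high_RA") as.integer(values > t) else
        as.integer(values <= t)
      tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
      fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
      den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
      m <- if (den == 0) 0 else (tp * tn - fp * fn) / den
      if (m > best$mcc + 1e-12) best <- list(mcc = m, threshold = t,
                                             polarity = pol)
    }
  }
  best
}

# Exact Shapley values of an rf_model's RA probability by enumeration over
# ALL feature subsets (feasible for <= ~10 features), with the
# path-dependent value function reimplemented in plain R.
brute_shapley <- function(model, X) {
  trees <- model$trees
  p <- ncol(X)
  expect_tree <- function(tr, x, inS, node = 1) {
    f <- tr$feature[node]
    if (f < 0) return(tr$p1[node])
    if (inS[f + 1]) {
      nxt <- if (x[f + 1] <= tr$threshold[node]) tr$left[node] else
        tr$right[node]
      return(expect_tree(tr, x, inS, nxt + 1))
    }
    nl <- tr$n[tr$left[node] + 1]; nr <- tr$n[tr$right[node] + 1]
    (nl * expect_tree(tr, x, inS, tr$left[node] + 1) +
       nr * expect_tree(tr, x, inS, tr$right[node] + 1)) / (nl + nr)
  }
  v <- function(x, S) {
    inS <- rep(FALSE, p); inS[S] <- TRUE
    mean(vapply(trees, function(tr) expect_tree(tr, x, inS), numeric(1)))
  }
  phi <- matrix(0, nrow(X), p)
  subsets <- lapply(0:(2^p - 1), function(mask) which(bitwAnd(mask, 2^(0:(p - 1))) > 0))
  for (i in seq_len(nrow(X))) {
    vals <- vapply(subsets, function(S) v(X[i, ], S), numeric(1))
    names(vals) <- vapply(subsets, function(S) paste(S, collapse = ","), "")
    for (j in seq_len(p)) {
      tot <- 0
      for (k in seq_along(subsets)) {
        S <- subsets[[k]]
        if (j %in% S) next
        w <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
        withj <- paste(sort(c(S, j)), collapse = ",")
        tot <- tot + w * (vals[[withj]] - vals[[k]])
      }
      phi[i, j] <- tot
    }
  }
  list(values = phi, base_value = v(X[1, ], integer(0)))
}

# Uniform draw from a search space (wraps the package-internal sampler).
ga_random_individual_for_tests <- function(space, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  synometab:::ga_random_individual(space)
}

# Tiny deterministic labelled matrix for IO / algebra tests.
toy_matrix <- function() {
  bin_matrix(matrix(c(1.5, 2.25, 3.125, 10, 20, 30), nrow = 3,
                    dimnames = list(NULL, c("Alanine [1.4800]",
                                            "D-Glucose [3.7708]"))),
             labels = c("OA", "OA", "RA"),
             sample_ids = c("p1", "p2", "p3"))
}

# Scaled cohort split into screened pieces; memoised per seed to avoid
# recomputing inside a test file.
screened_cohort <- local({
  cache <- list()
  function(seed = 3) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      sim <- simulate_cohort(seed = seed)
      scaled <- normalize_bins(sim$matrix, "minmax")
      sc <- screen_bins(scaled)
      rest <- subset_bins(scaled, sc$rest_bins)
      cache[[key]] <<- list(sim = sim, scaled = scaled, screen = sc,
                            rest = rest, ranking = rfe_rank(rest))
    }
    cache[[key]]
  }
})
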