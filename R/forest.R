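#' Hyperparameter set for the RFE + forest classifier
#'
#' Bundles the number of bins retained by SVM-RFE with the six ensemble
#' hyperparameters that the genetic algorithm tunes.
#'
#' @param n_rfe bins retained by RFE before classification.
#' @param n_est number of trees in the ensemble.
#' @param max_depth maximum tree depth (root = depth 0).
#' @param min_split minimum samples a node needs to be split.
#' @param min_leaf minimum samples in each child.
#' @param n_f feature-subset rule per tree: `"log2"` (`floor(log2(n_rfe))`),
#'   `"sqrt"` (`floor(sqrt(n_rfe))`), or an explicit count.
#' @param crit split criterion: `"gini"`, `"entropy"`, or `"log_loss"`
#'   (log_loss is the entropy impurity; the two are mathematically the
#'   same criterion for classification trees).
#' @return list of class `hyper_params`.
#' @examples
#' # the best-performing configuration reported for the MTBLS564 cohort
#' hp <- hyper_params(n_rfe = 50, n_est = 100, max_depth = 6,
#'                    min_split = 10, min_leaf = 6, n_f = "log2",
#'                    crit = "log_loss")
#' resolve_n_f(hp)   # floor(log2(50)) = 5
#' @export
hyper_params <- function(n_rfe, n_est, max_depth, min_split, min_leaf,
                         n_f, crit = c("gini", "entropy", "log_loss")) {
  crit <- match.arg(crit)
  stopifnot(n_rfe >= 1, n_est >= 1, max_depth >= 1, min_split >= 1,
            min_leaf >= 1)
  if (!(identical(n_f, "log2") || identical(n_f, "sqrt") ||
        (is.numeric(n_f) && n_f >= 1))) {
    stop("n_f must be 'log2', 'sqrt' or a positive count")
  }
  structure(list(n_rfe = as.integer(n_rfe), n_est = as.integer(n_est),
                 max_depth = as.integer(max_depth),
                 min_split = as.integer(min_split),
                 min_leaf = as.integer(min_leaf), n_f = n_f, crit = crit),
            class = "hyper_params")
}

#' @rdname hyper_params
#' @param params a `hyper_params`.
#' @return `resolve_n_f()`: the per-tree feature-subset size implied by the
#'   rule, clamped to `[1, n_rfe]`.
#' @export
resolve_n_f <- function(params) {
  n <- params$n_rfe
  k <- if (identical(params$n_f, "log2")) {
    floor(log2(n))
  } else if (identical(params$n_f, "sqrt")) {
    floor(sqrt(n))
  } else {
    as.integer(params$n_f)
  }
  max(1L, min(as.integer(k), n))
}

# canonical cache/serialization key for a hyperparameter set
hp_key <- function(params) {
  paste(params$n_rfe, params$n_est, params$max_depth, params$min_split,
        params$min_leaf, params$n_f, params$crit, sep = "|")
}

#' Fit the bagged tree ensemble
#'
#' Trains `n_est` classification trees, each on a bootstrap resample of the
#' samples and a random subspace of `resolve_n_f(params)` bins drawn once
#' per tree, split by the requested impurity with the depth / split / leaf
#' constraints. The predicted RA probability of the ensemble is the mean of
#' the per-tree leaf class fractions.
#'
#' @param matrix a scaled [bin_matrix()] restricted to the retained bins.
#' @param params a [hyper_params()]. `n_rfe` is not used here (the matrix
#'   is already restricted); the subset rule resolves against the matrix
#'   width.
#' @param seed integer seed for bootstrap and subspace draws.
#' @return list of class `rf_model` with `trees`, `params`, `bin_ids`.
#' @export
rf_fit <- function(matrix, params, seed = 1) {
  validate_bin_matrix(matrix)
  stopifnot(inherits(params, "hyper_params"))
  p_use <- params
  p_use$n_rfe <- ncol(matrix$values)
  mtry <- resolve_n_f(p_use)
  crit_code <- if (params$crit == "gini") 0L else 1L
  trees <- .cpp_forest_fit(matrix$values, class_code(matrix$labels),
                           params$n_est, mtry, params$max_depth,
                           params$min_split, params$min_leaf, crit_code,
                           as.integer(seed))
  structure(list(trees = trees, params = params,
                 bin_ids = matrix$bins$bin_id),
            class = "rf_model")
}

#' Predict RA probabilities from a fitted ensemble
#'
#' @param object an `rf_model`.
#' @param matrix a [bin_matrix()] over the same bins (same order).
#' @param ... unused.
#' @return numeric vector of RA (class 1) probabilities; a sample is
#'   classified RA when its probability is >= 0.5.
#' @export
predict.rf_model <- function(object, matrix, ...) {
  if (!identical(object$bin_ids, matrix$bins$bin_id)) {
    stop("model and matrix bins do not match")
  }
  .cpp_forest_predict(object$trees, matrix$values)
}

#' Matthews correlation coefficient from confusion counts
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the
#' convention that a zero denominator yields 0 (random-guess equivalent).
#' RA is the positive class throughout the package.
#'
#' @param tp,tn,fp,fn confusion counts (non-negative, total >= 1).
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn >= 1)
  mcc_counts(as.numeric(tp), as.numeric(tn), as.numeric(fp), as.numeric(fn))
}

#' Pooled binary classification metrics
#'
#' Computes MCC, accuracy, precision, recall, F1 and ROC-AUC from pooled
#' predictions, with RA as the positive class. Probability >= 0.5 predicts
#' RA. Precision, recall and F1 follow the 0/0 -> 0 convention; ROC-AUC is
#' computed from the pooled probabilities (pROC), and is 0.5 when the
#' probabilities are all identical.
#'
#' @param labels true OA/RA labels.
#' @param prob predicted RA probabilities.
#' @return list of class `cv_metrics`: `mcc`, `accuracy`, `precision`,
#'   `recall`, `f1`, `roc_auc`, plus the pooled confusion counts.
#' @export
classification_metrics <- function(labels, prob) {
  y <- class_code(factor(as.character(labels), levels = c("OA", "RA")))
  pred <- as.integer(prob >= 0.5)
  tp <- sum(pred == 1 & y == 1)
  tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  auc <- if (length(unique(prob)) < 2) 0.5 else {
    as.numeric(pROC::auc(pROC::roc(response = y, predictor = prob,
                                   levels = c(0, 1), direction = "<",
                                   quiet = TRUE)))
  }
  structure(list(mcc = mcc(tp, tn, fp, fn),
                 accuracy = (tp + tn) / length(y),
                 precision = precision, recall = recall, f1 = f1,
                 roc_auc = auc,
                 confusion = c(tp = tp, tn = tn, fp = fp, fn = fn)),
            class = "cv_metrics")
}

#' Leave-one-out cross-validation of the ensemble
#'
#' Runs exactly `n_samples` folds: in each, the ensemble is trained on the
#' other `n - 1` samples (with a fold seed derived deterministically from
#' the master seed) and predicts the held-out sample's RA probability.
#' Metrics are computed once on the pooled held-out predictions.
#'
#' @param matrix a scaled [bin_matrix()] restricted to the bins to use.
#' @param params a [hyper_params()].
#' @param seed master seed; fold `i` trains with seed `seed * 1000 + i`.
#' @return a `cv_metrics` list (see [classification_metrics()]) with an
#'   extra `predictions` data.frame (`sample_id`, `label`, `prob_RA`).
#' @export
rf_loocv <- function(matrix, params, seed = 1) {
  validate_bin_matrix(matrix)
  n <- nrow(matrix$values)
  if (n < 3) stop("LOOCV needs at least 3 samples")
  prob <- numeric(n)
  for (i in seq_len(n)) {
    train <- bin_matrix(matrix$values[-i, , drop = FALSE],
                        labels = matrix$labels[-i],
                        bins = matrix$bins,
                        sample_ids = matrix$sample_ids[-i])
    fold_seed <- as.integer((as.numeric(seed) * 1000 + i) %% 2147483647)
    fit <- rf_fit(train, params, seed = fold_seed)
    prob[i] <- .cpp_forest_predict(fit$trees,
                                   matrix$values[i, , drop = FALSE])
  }
  out <- classification_metrics(matrix$labels, prob)
  out$predictions <- data.frame(sample_id = matrix$sample_ids,
                                label = as.character(matrix$labels),
                                prob_RA = prob, stringsAsFactors = FALSE)
  out
}
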