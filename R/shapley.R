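#' Exact Shapley attribution for a fitted ensemble
#'
#' Computes per-sample, per-bin Shapley values of the ensemble's RA
#' probability (probability scale). The value function is the standard
#' path-dependent conditional expectation: features absent from a coalition
#' are marginalized along each tree by the bootstrap node proportions.
#' Because each tree depends only on its own split features, its Shapley
#' values are computed exactly by enumerating the subsets of those features
#' and are summed across trees (linearity of the Shapley value; bins a tree
#' never splits on are dummy players with zero attribution).
#'
#' Local accuracy holds by construction: for every sample,
#' `base_value + sum(shap_values[i, ])` equals the model's predicted RA
#' probability.
#'
#' @param model an [rf_fit()] model.
#' @param matrix the [bin_matrix()] of retained bins the model was trained
#'   on (same bins, same order).
#' @return list of class `attribution_result`: `shap_values`
#'   (n_samples x n_bins, dimnames sample x bin_id), `base_value`,
#'   `scale = "probability"`, `prediction` (per-sample RA probability),
#'   and `bins` metadata.
#' @export
shapley_attribution <- function(model, matrix) {
  stopifnot(inherits(model, "rf_model"))
  validate_bin_matrix(matrix)
  if (!identical(model$bin_ids, matrix$bins$bin_id)) {
    stop("model and matrix bins do not match")
  }
  res <- .cpp_forest_shapley(model$trees, matrix$values)
  sv <- res$values
  dimnames(sv) <- list(matrix$sample_ids, matrix$bins$bin_id)
  structure(list(shap_values = sv, base_value = res$base_value,
                 scale = "probability",
                 prediction = .cpp_forest_predict(model$trees,
                                                  matrix$values),
                 values = matrix$values, bins = matrix$bins),
            class = "attribution_result")
}

#' Rank bins by mean absolute Shapley value
#'
#' Orders the retained bins by mean |SHAP| (descending) and annotates each
#' with its direction: `"RA"` when higher intensities push the prediction
#' toward RA (positive correlation between the bin's values and its
#' attributions), `"OA"` otherwise. A metabolite represented by several
#' bins appears once per bin.
#'
#' @param result an `attribution_result` from [shapley_attribution()].
#' @param k number of top bins (default 20).
#' @return data.frame with `rank`, `bin_id`, `metabolite_name`,
#'   `ppm_center`, `mean_abs_shap`, `direction`.
#' @export
rank_attributions <- function(result, k = 20) {
  stopifnot(inherits(result, "attribution_result"))
  n_bins <- ncol(result$shap_values)
  if (k < 1 || k > n_bins) stop("k must lie in 1..", n_bins)
  mas <- colMeans(abs(result$shap_values))
  direction <- vapply(seq_len(n_bins), function(j) {
    s <- result$shap_values[, j]
    if (stats::sd(s) == 0 || stats::sd(result$values[, j]) == 0) return("none")
    if (stats::cor(result$values[, j], s) >= 0) "RA" else "OA"
  }, character(1))
  ord <- order(-mas, result$bins$bin_id)[seq_len(k)]
  data.frame(rank = seq_len(k),
             bin_id = result$bins$bin_id[ord],
             metabolite_name = result$bins$metabolite_name[ord],
             ppm_center = result$bins$ppm_center[ord],
             mean_abs_shap = unname(mas[ord]),
             direction = direction[ord],
             stringsAsFactors = FALSE)
}

#' Compare PLS-DA and ML marker selections
#'
#' Collapses both selections to metabolite names and reports, per disease,
#' the metabolites found by both methods, by each alone, and — across
#' diseases — the *ambiguous* metabolites that appear in the OA selection
#' of one method and the RA selection of the other (or both diseases of
#' either method).
#'
#' @param plsda_ranking result of [rank_bins()] (a list with `ranking_OA`
#'   and `ranking_RA` data.frames carrying `metabolite_name`).
#' @param ml_ranking result of [rank_attributions()] (directions split the
#'   bins into OA- and RA-associated).
#' @return list of class `marker_comparison` with per-disease elements
#'   `OA` and `RA` (each `both`, `plsda_only`, `ml_only`) and `ambiguous`.
#' @export
compare_selections <- function(plsda_ranking, ml_ranking) {
  p_oa <- unique(plsda_ranking$ranking_OA$metabolite_name)
  p_ra <- unique(plsda_ranking$ranking_RA$metabolite_name)
  m_oa <- unique(ml_ranking$metabolite_name[ml_ranking$direction == "OA"])
  m_ra <- unique(ml_ranking$metabolite_name[ml_ranking$direction == "RA"])
  set_cmp <- function(a, b) {
    list(both = sort(intersect(a, b)),
         plsda_only = sort(setdiff(a, b)),
         ml_only = sort(setdiff(b, a)))
  }
  all_oa <- union(p_oa, m_oa)
  all_ra <- union(p_ra, m_ra)
  structure(list(OA = set_cmp(p_oa, m_oa), RA = set_cmp(p_ra, m_ra),
                 ambiguous = sort(intersect(all_oa, all_ra))),
            class = "marker_comparison")
}

#' Run the full pipeline and summarize it
#'
#' End-to-end driver: normalization selection, PLS-DA ranking, stump
#' screening with separation metrics for the perfect bins, SVM-RFE + GA
#' tuning of the ensemble on the non-perfect bins, LOOCV metrics with and
#' without RFE, Shapley attribution of the final model (trained on all
#' samples), and the PLS-DA vs ML marker comparison. All seeds and the
#' configuration are recorded in the summary, which is JSON-serializable
#' and byte-stable for a fixed input and seed.
#'
#' @param matrix a raw [bin_matrix()].
#' @param space a [search_space()].
#' @param config a [ga_config()]; scale `n_pop` / `n_gen` down for quick
#'   runs.
#' @param top_k top bins reported from PLS-DA (per class) and SHAP.
#' @return list of class `pipeline_summary`; see Details in the vignette.
#' @export
run_report <- function(matrix, space = search_space(),
                       config = ga_config(), top_k = 20) {
  validate_bin_matrix(matrix)
  norm <- select_normalization(matrix)
  scaled <- norm$scaled

  pls <- fit_plsda(scaled, n_components = 2)
  pls_rank <- rank_bins(pls, k = min(10, floor(ncol(scaled$values) / 2)))

  screen <- screen_bins(scaled)
  perfect_metrics <- lapply(screen$perfect_bins, function(id) {
    j <- match(id, scaled$bins$bin_id)
    sm <- separation_metrics(scaled$values[, j], scaled$labels)
    data.frame(bin_id = id,
               metabolite_name = scaled$bins$metabolite_name[j],
               d = sm$d, sd_OA = sm$sd_OA, sd_RA = sm$sd_RA,
               fdr = sm$fdr, three_sigma_pass = sm$three_sigma_pass,
               stringsAsFactors = FALSE)
  })
  perfect_metrics <- if (length(perfect_metrics)) {
    do.call(rbind, perfect_metrics)
  } else {
    NULL
  }

  rest <- subset_bins(scaled, screen$rest_bins)
  ga <- run_ga(rest, space, config)
  with_rfe <- ga$best_metrics

  # counterfactual: same ensemble hyperparameters, no feature elimination
  no_rfe <- rf_loocv(rest, ga$best, seed = config$seed)

  model <- rf_fit(subset_bins(rest, with_rfe$retained_bins), ga$best,
                  seed = config$seed)
  attr_res <- shapley_attribution(model,
                                  subset_bins(rest, with_rfe$retained_bins))
  shap_rank <- rank_attributions(attr_res,
                                 k = min(top_k,
                                         length(with_rfe$retained_bins)))
  comparison <- compare_selections(pls_rank, shap_rank)

  structure(list(
    n_samples = nrow(matrix$values),
    class_summary = class_summary(matrix),
    normalization = list(method = norm$method,
                         silhouette = norm$silhouette,
                         candidates = norm$candidates,
                         pc_variance = norm$pc_variance),
    plsda = pls_rank,
    stump = list(perfect_bins = screen$perfect_bins,
                 perfect_metrics = perfect_metrics,
                 n_rest = length(screen$rest_bins)),
    best_params = ga$best[c("n_rfe", "n_est", "max_depth", "min_split",
                            "min_leaf", "n_f", "crit")],
    ga = list(best_fitness = ga$best_fitness,
              n_evaluated = ga$n_evaluated, history = ga$history),
    metrics_with_rfe = with_rfe[c("mcc", "accuracy", "precision", "recall",
                                  "f1", "roc_auc")],
    metrics_without_rfe = no_rfe[c("mcc", "accuracy", "precision", "recall",
                                   "f1", "roc_auc")],
    loocv_predictions = with_rfe$predictions,
    shap = list(scale = attr_res$scale, base_value = attr_res$base_value,
                top = shap_rank),
    comparison = comparison,
    config = list(ga = unclass(config), seed = config$seed)
  ), class = "pipeline_summary")
}
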