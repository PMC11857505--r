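#' Column-wise normalization of a bin matrix
#'
#' The five candidate scalings evaluated before analysis. All operate per
#' bin (column):
#'
#' * `zscore`: \eqn{(x - mean) / sd}
#' * `minmax`: \eqn{(x - min) / (max - min)}, mapping each bin into `[0, 1]`
#' * `maxabs`: \eqn{x / max |x|}
#' * `robust`: \eqn{(x - median) / IQR} (25th-75th percentile range)
#' * `median_pareto`: median centering followed by division by the square
#'   root of the bin's standard deviation (Pareto scaling)
#'
#' @param matrix a [bin_matrix()].
#' @param method one of `"zscore"`, `"minmax"`, `"maxabs"`, `"robust"`,
#'   `"median_pareto"`.
#' @return the scaled `bin_matrix`.
#' @export
normalize_bins <- function(matrix,
                           method = c("zscore", "minmax", "maxabs", "robust",
                                      "median_pareto")) {
  validate_bin_matrix(matrix)
  method <- match.arg(method)
  v <- matrix$values
  scaled <- switch(
    method,
    zscore = {
      s <- apply(v, 2, stats::sd)
      check_spread(s, matrix, "standard deviation")
      sweep(sweep(v, 2, colMeans(v)), 2, s, "/")
    },
    minmax = {
      rng <- apply(v, 2, range)
      s <- rng[2, ] - rng[1, ]
      check_spread(s, matrix, "range")
      sweep(sweep(v, 2, rng[1, ]), 2, s, "/")
    },
    maxabs = {
      s <- apply(abs(v), 2, max)
      check_spread(s, matrix, "max absolute value")
      sweep(v, 2, s, "/")
    },
    robust = {
      med <- apply(v, 2, stats::median)
      s <- apply(v, 2, stats::IQR)
      check_spread(s, matrix, "IQR")
      sweep(sweep(v, 2, med), 2, s, "/")
    },
    median_pareto = {
      med <- apply(v, 2, stats::median)
      s <- sqrt(apply(v, 2, stats::sd))
      check_spread(s, matrix, "sqrt(sd)")
      sweep(sweep(v, 2, med), 2, s, "/")
    }
  )
  out <- matrix
  out$values <- scaled
  out
}

check_spread <- function(s, matrix, what) {
  bad <- which(!is.finite(s) | s == 0)
  if (length(bad)) {
    stop("zero ", what, " in bin(s): ",
         paste(utils::head(matrix$bins$bin_id[bad], 5), collapse = ", "))
  }
}

#' Principal component exploration
#'
#' Mean-centers the (already scaled) bin matrix and decomposes it, returning
#' per-component scores and the fraction of total variance each component
#' captures. No re-scaling is applied: the scaling has been chosen upstream.
#'
#' @param matrix a scaled [bin_matrix()].
#' @param n_components number of components to keep; at most
#'   `min(n_samples - 1, n_bins)`.
#' @return list with `scores` (n_samples x n_components) and `pc_variance`
#'   (fraction of total variance per component, non-increasing).
#' @export
pca_explore <- function(matrix, n_components = 3) {
  validate_bin_matrix(matrix)
  kmax <- min(nrow(matrix$values) - 1L, ncol(matrix$values))
  if (n_components < 1 || n_components > kmax) {
    stop("n_components must lie in 1..", kmax)
  }
  p <- stats::prcomp(matrix$values, center = TRUE, scale. = FALSE)
  varfrac <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(n_components), drop = FALSE],
       pc_variance = varfrac[seq_len(n_components)])
}

#' Silhouette score of the OA/RA labelling
#'
#' Mean silhouette width over samples, computed with Euclidean distance in
#' the full scaled bin space and the known diagnosis labels as the cluster
#' assignment. Measures how well the chosen scaling separates the two
#' patient groups.
#'
#' @param matrix a scaled [bin_matrix()].
#' @param clusters optional alternative integer cluster assignment (for
#'   unsupervised use); defaults to the OA/RA labels.
#' @return mean silhouette width, in `[-1, 1]`.
#' @export
silhouette_by_label <- function(matrix, clusters = NULL) {
  validate_bin_matrix(matrix)
  if (is.null(clusters)) clusters <- as.integer(matrix$labels)
  if (min(table(clusters)) < 2) {
    stop("each class needs at least 2 members for a silhouette score")
  }
  sil <- cluster::silhouette(clusters, stats::dist(matrix$values))
  mean(sil[, "sil_width"])
}

#' Select the normalization that best separates the classes
#'
#' Applies every candidate scaling, scores each by the label-based
#' silhouette, and returns the report of the silhouette-maximizing method.
#' Ties are broken in the listed candidate order; a method whose
#' preconditions fail (e.g. a zero denominator) is skipped with a warning.
#'
#' @param matrix a raw [bin_matrix()].
#' @param methods candidate methods, in tie-break order.
#' @param n_components components to report from the PCA exploration.
#' @return list of class `normalization_report`: `method`, `scaled`
#'   (the winning scaled matrix), `silhouette`, `pc_variance`, and
#'   `candidates` (data.frame of every evaluated method and score).
#' @export
select_normalization <- function(matrix,
                                 methods = c("zscore", "minmax", "maxabs",
                                             "robust", "median_pareto"),
                                 n_components = 3) {
  validate_bin_matrix(matrix)
  reports <- list()
  scores <- rep(NA_real_, length(methods))
  names(scores) <- methods
  for (m in methods) {
    res <- tryCatch({
      scaled <- normalize_bins(matrix, m)
      list(scaled = scaled, sil = silhouette_by_label(scaled))
    }, error = function(e) {
      warning("normalization '", m, "' skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      reports[[m]] <- res
      scores[m] <- res$sil
    }
  }
  if (!length(reports)) stop("every normalization method failed")
  best <- names(scores)[which.max(scores)]  # which.max: first max wins ties
  kmax <- min(nrow(matrix$values) - 1L, ncol(matrix$values))
  pcv <- pca_explore(reports[[best]]$scaled,
                     min(n_components, kmax))$pc_variance
  structure(list(method = best,
                 scaled = reports[[best]]$scaled,
                 silhouette = scores[[best]],
                 pc_variance = pcv,
                 candidates = data.frame(method = methods,
                                         silhouette = unname(scores),
                                         stringsAsFactors = FALSE)),
            class = "normalization_report")
}

#' @export
print.normalization_report <- function(x, ...) {
  cat("normalization_report: selected '", x$method, "' (silhouette ",
      sprintf("%.4f", x$silhouette), ")\n", sep = "")
  print(x$candidates)
  invisible(x)
}
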