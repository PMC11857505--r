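#' SVM recursive feature elimination ranking
#'
#' Repeatedly fits a linear-kernel soft-margin SVM (cost fixed at 1) on the
#' remaining bins, scores each bin by its squared weight in the separating
#' hyperplane, and removes the single lowest-scoring bin, until one bin
#' remains. Because exactly one bin is removed per iteration, the process
#' for any retention size `n_keep` is a prefix of this full elimination:
#' the ranking is computed once and reused.
#'
#' Ties in squared weight are broken by removing the bin with the larger
#' column index, so the procedure is deterministic.
#'
#' @param matrix a scaled [bin_matrix()] (typically the non-perfect bins).
#' @return character vector of bin_ids ordered from most important
#'   (eliminated last) to least important (eliminated first).
#' @export
rfe_rank <- function(matrix) {
  validate_bin_matrix(matrix)
  y <- factor(matrix$labels)
  X <- matrix$values
  ids <- matrix$bins$bin_id
  alive <- seq_len(ncol(X))
  elim <- integer(0)
  while (length(alive) > 1) {
    fit <- tryCatch(
      e1071::svm(X[, alive, drop = FALSE], y, kernel = "linear", cost = 1,
                 scale = FALSE, type = "C-classification"),
      error = function(e) stop("SVM fit failed during RFE: ",
                               conditionMessage(e))
    )
    w <- drop(crossprod(fit$coefs, fit$SV))
    sq <- w^2
    # lowest squared weight goes; ties resolved toward the later column
    worst <- which(sq == min(sq))
    worst <- worst[length(worst)]
    elim <- c(elim, alive[worst])
    alive <- alive[-worst]
  }
  ids[rev(c(elim, alive))]
}

#' Retain the top bins under SVM-RFE
#'
#' @param matrix a scaled [bin_matrix()].
#' @param n_keep number of bins to retain (1..n_bins).
#' @param ranking optional precomputed [rfe_rank()] result for `matrix`.
#' @return character vector of the `n_keep` retained bin_ids, in ranking
#'   order.
#' @export
rfe_select <- function(matrix, n_keep, ranking = NULL) {
  validate_bin_matrix(matrix)
  n_bins <- ncol(matrix$values)
  if (n_keep < 1 || n_keep > n_bins) stop("n_keep must lie in 1..", n_bins)
  if (is.null(ranking)) ranking <- rfe_rank(matrix)
  ranking[seq_len(n_keep)]
}
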