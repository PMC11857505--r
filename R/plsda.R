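#' Partial least squares discriminant analysis (PLS1, NIPALS)
#'
#' Fits a PLS regression of the 0/1 class code (OA = 0, RA = 1) on the
#' scaled bin matrix using the classical NIPALS deflation algorithm with a
#' single response column. The returned per-bin regression coefficients are
#' signed: a negative coefficient means the bin is elevated in OA, a
#' positive one that it is elevated in RA.
#'
#' For a single component the coefficient vector is proportional to
#' `t(X_c) %*% y_c` (the covariance of each centered column with the
#' centered class code), which the tests use as an independent closed form.
#'
#' @param matrix a scaled [bin_matrix()].
#' @param n_components number of latent components (default 2); at most
#'   `n_samples - 1`.
#' @return list of class `plsda_fit`: `n_components`, `scores`
#'   (n_samples x n_components), `weights` (orthonormal X-weights),
#'   `coefficients` (named per-bin signed coefficients), `intercept`,
#'   `fitted`, and `bins` metadata.
#' @export
fit_plsda <- function(matrix, n_components = 2) {
  validate_bin_matrix(matrix)
  y <- class_code(matrix$labels)
  if (length(unique(y)) < 2) stop("degenerate response: one class only")
  if (n_components < 1 || n_components > nrow(matrix$values) - 1) {
    stop("n_components must lie in 1..", nrow(matrix$values) - 1)
  }
  X <- matrix$values
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2, xbar)
  yc <- y - ybar

  n_bins <- ncol(X)
  W <- matrix(0, n_bins, n_components)  # X-weights (orthonormal)
  P <- matrix(0, n_bins, n_components)  # X-loadings
  Tm <- matrix(0, nrow(X), n_components)
  q <- numeric(n_components)
  Xd <- Xc
  yd <- yc
  for (a in seq_len(n_components)) {
    w <- crossprod(Xd, yd)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      # X carries no remaining covariance with the response
      n_components <- a - 1L
      if (n_components == 0L) stop("response is uncorrelated with every bin")
      W <- W[, seq_len(n_components), drop = FALSE]
      P <- P[, seq_len(n_components), drop = FALSE]
      Tm <- Tm[, seq_len(n_components), drop = FALSE]
      q <- q[seq_len(n_components)]
      break
    }
    w <- w / nw
    t_a <- Xd %*% w
    tt <- sum(t_a^2)
    p_a <- crossprod(Xd, t_a)[, 1] / tt
    q_a <- sum(yd * t_a) / tt
    Xd <- Xd - tcrossprod(t_a, p_a)
    yd <- yd - q_a * t_a
    W[, a] <- w
    P[, a] <- p_a
    Tm[, a] <- t_a
    q[a] <- q_a
  }
  # regression coefficients on the original (centered) X scale
  B <- W %*% solve(crossprod(P, W), q)
  coef <- drop(B)
  names(coef) <- matrix$bins$bin_id
  intercept <- ybar - sum(xbar * coef)
  structure(list(n_components = n_components, scores = Tm, weights = W,
                 loadings = P, coefficients = coef, intercept = intercept,
                 fitted = drop(X %*% coef) + intercept,
                 bins = matrix$bins),
            class = "plsda_fit")
}

#' Rank bins by PLS-DA coefficient
#'
#' Splits the signed coefficients into the `k` most OA-associated bins
#' (most negative coefficients, ascending) and the `k` most RA-associated
#' bins (most positive, descending). Ties are broken by `bin_id` lexical
#' order and flagged.
#'
#' @param fit a `plsda_fit` from [fit_plsda()].
#' @param k bins per class list (default 10); at most `n_bins / 2`.
#' @return list with data.frames `ranking_OA` and `ranking_RA` (columns
#'   `rank`, `bin_id`, `metabolite_name`, `ppm_center`, `coefficient`) and
#'   logical `degenerate_ties`.
#' @export
rank_bins <- function(fit, k = 10) {
  stopifnot(inherits(fit, "plsda_fit"))
  n_bins <- length(fit$coefficients)
  if (k > n_bins / 2) stop("k must not exceed n_bins / 2")
  df <- data.frame(bin_id = fit$bins$bin_id,
                   metabolite_name = fit$bins$metabolite_name,
                   ppm_center = fit$bins$ppm_center,
                   coefficient = unname(fit$coefficients),
                   stringsAsFactors = FALSE)
  ord_oa <- order(df$coefficient, df$bin_id)          # most negative first
  ord_ra <- order(-df$coefficient, df$bin_id)         # most positive first
  mk <- function(ord) {
    out <- df[ord[seq_len(k)], , drop = FALSE]
    out <- cbind(rank = seq_len(k), out)
    rownames(out) <- NULL
    out
  }
  ties <- anyDuplicated(df$coefficient) > 0
  list(ranking_OA = mk(ord_oa), ranking_RA = mk(ord_ra),
       degenerate_ties = ties)
}
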