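#' Best decision stump for one bin
#'
#' Sweeps every candidate threshold (midpoints of consecutive sorted unique
#' values) and both polarities, scoring each one-split classifier by the
#' Matthews correlation coefficient, and returns the maximizer. Among
#' thresholds of equal MCC the one with the largest margin (distance to the
#' nearest observation) wins, making the choice deterministic and placing
#' the boundary centrally in the empty interval. MCC is defined as 0
#' whenever a factor of its denominator is 0 (the random-guess convention).
#'
#' Because only the ordering of `values` enters, the result is invariant
#' under strictly increasing transforms of the intensities.
#'
#' @param values numeric vector, one intensity per sample.
#' @param labels OA/RA labels, same length.
#' @return list of class `stump_result`: `threshold`, `polarity`
#'   (`"high_RA"` if values above the threshold predict RA, else
#'   `"high_OA"`), `mcc`, `margin`.
#' @export
stump_mcc <- function(values, labels) {
  labels <- factor(as.character(labels), levels = c("OA", "RA"))
  if (anyNA(labels)) stop("labels must be OA/RA")
  if (nlevels(droplevels(labels)) < 2) stop("both classes must be present")
  if (any(!is.finite(values))) stop("values must be finite")
  y <- as.integer(labels == "RA")
  u <- sort(unique(values))
  if (length(u) < 2) {
    return(structure(list(threshold = u[1], polarity = "high_RA",
                          mcc = 0, margin = 0), class = "stump_result"))
  }
  thr <- (u[-length(u)] + u[-1]) / 2
  n1 <- sum(y)
  n0 <- length(y) - n1
  # counts of RA (and total) strictly above each threshold
  above_ra <- vapply(thr, function(t) sum(y[values > t]), integer(1))
  above_n <- vapply(thr, function(t) sum(values > t), integer(1))

  # polarity high_RA: predict RA when value > threshold
  tp <- above_ra; fp <- above_n - above_ra
  fn <- n1 - tp; tn <- n0 - fp
  mcc_hi <- mcc_counts(tp, tn, fp, fn)
  # polarity high_OA: predict RA when value <= threshold
  tp2 <- n1 - above_ra; fp2 <- n0 - (above_n - above_ra)
  fn2 <- above_ra; tn2 <- above_n - above_ra
  mcc_lo <- mcc_counts(tp2, tn2, fp2, fn2)

  margin <- (u[-1] - u[-length(u)]) / 2
  cand <- data.frame(threshold = c(thr, thr),
                     polarity = rep(c("high_RA", "high_OA"), each = length(thr)),
                     mcc = c(mcc_hi, mcc_lo), margin = c(margin, margin))
  best_mcc <- max(cand$mcc)
  top <- cand[cand$mcc >= best_mcc - 1e-12, , drop = FALSE]
  pick <- top[which.max(top$margin), , drop = FALSE]
  structure(list(threshold = pick$threshold, polarity = pick$polarity,
                 mcc = pick$mcc, margin = pick$margin),
            class = "stump_result")
}

# vectorized MCC from confusion counts; 0-over-0 convention -> 0
mcc_counts <- function(tp, tn, fp, fn) {
  num <- tp * tn - fp * fn
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  ifelse(den == 0, 0, num / den)
}

#' Screen every bin with a decision stump
#'
#' Applies [stump_mcc()] to each bin of a cleaned, scaled matrix and splits
#' the bins into the *perfect* set (stump MCC exactly 1.0, i.e. a clear
#' decision boundary with non-overlapping class supports) and the
#' remainder, which is what the multivariate RFE + forest stage operates on.
#'
#' @param matrix a scaled [bin_matrix()].
#' @return list of class `stump_screen`: `results` (data.frame of per-bin
#'   `bin_id`, `metabolite_name`, `ppm_center`, `threshold`, `polarity`,
#'   `mcc`, `margin`, sorted by decreasing MCC), `perfect_bins` (bin_ids
#'   with MCC 1), `rest_bins` (all other bin_ids).
#' @export
screen_bins <- function(matrix) {
  validate_bin_matrix(matrix)
  res <- lapply(seq_len(ncol(matrix$values)), function(j) {
    s <- stump_mcc(matrix$values[, j], matrix$labels)
    data.frame(bin_id = matrix$bins$bin_id[j],
               metabolite_name = matrix$bins$metabolite_name[j],
               ppm_center = matrix$bins$ppm_center[j],
               threshold = s$threshold, polarity = s$polarity,
               mcc = s$mcc, margin = s$margin, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  perfect <- res$bin_id[res$mcc >= 1 - 1e-12]
  ord <- order(-res$mcc, res$bin_id)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  structure(list(results = res, perfect_bins = perfect,
                 rest_bins = setdiff(matrix$bins$bin_id, perfect)),
            class = "stump_screen")
}

#' Class-separation metrics for one bin
#'
#' One-dimensional centroid distance, per-class standard deviations
#' (sample, n-1 denominator), the three-sigma separation verdict, and the
#' Fisher discriminant ratio for a single metabolite bin.
#'
#' @param values numeric vector of (scaled) intensities.
#' @param labels OA/RA labels; at least 2 samples per class.
#' @return list of class `separation_metrics`: `d` (centroid distance),
#'   `sd_OA`, `sd_RA`, `three_sigma_pass`, `fdr`.
#' @seealso [fisher_ratio()], [three_sigma_pass()]
#' @export
separation_metrics <- function(values, labels) {
  labels <- factor(as.character(labels), levels = c("OA", "RA"))
  if (min(table(labels)) < 2) stop("need at least 2 samples per class")
  x_oa <- values[labels == "OA"]
  x_ra <- values[labels == "RA"]
  d <- abs(mean(x_oa) - mean(x_ra))
  sd_oa <- stats::sd(x_oa)
  sd_ra <- stats::sd(x_ra)
  structure(list(d = d, sd_OA = sd_oa, sd_RA = sd_ra,
                 three_sigma_pass = three_sigma_pass(d, sd_oa, sd_ra),
                 fdr = fisher_ratio(d, sd_oa, sd_ra)),
            class = "separation_metrics")
}

#' Fisher discriminant ratio from summary statistics
#'
#' The ratio of between-class variance (squared centroid distance) to
#' within-class variance (sum of the two class variances):
#' \eqn{FDR = d^2 / (sd_{OA}^2 + sd_{RA}^2)}. Defined as 0 when both class
#' variances are 0. This is the feature-separability FDR, not a false
#' discovery rate.
#'
#' @param d centroid distance (non-negative).
#' @param sd_OA,sd_RA per-class standard deviations.
#' @return the Fisher discriminant ratio.
#' @export
fisher_ratio <- function(d, sd_OA, sd_RA) {
  den <- sd_OA^2 + sd_RA^2
  ifelse(den > 0, d^2 / den, 0)
}

#' Three-sigma separation rule from summary statistics
#'
#' A bin passes when three times each class standard deviation stays below
#' the centroid distance: `3 * sd_OA < d` and `3 * sd_RA < d`.
#'
#' @inheritParams fisher_ratio
#' @return logical verdict.
#' @export
three_sigma_pass <- function(d, sd_OA, sd_RA) {
  (3 * sd_OA < d) & (3 * sd_RA < d)
}
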