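#' Labelled bin-intensity matrix
#'
#' The central container of the pipeline: a samples x bins intensity matrix
#' from binned NMR spectra of synovial fluid, together with OA/RA diagnosis
#' labels and per-bin metadata (metabolite name and ppm bin center).
#'
#' Orientation is fixed as samples-in-rows everywhere; readers for
#' bins-in-rows formats (see [read_maf()]) transpose on input. The label
#' coding convention used throughout the package is OA = 0, RA = 1, with RA
#' as the positive class of every classification metric.
#'
#' @param values numeric matrix, `n_samples x n_bins`; no missing values.
#' @param labels character or factor of length `n_samples` over
#'   `c("OA", "RA")`; both classes must be present.
#' @param bins data.frame with columns `bin_id` (unique), `metabolite_name`
#'   and `ppm_center` (numeric; `NA` allowed when the ppm center is unknown).
#'   Defaults are synthesized from `colnames(values)`.
#' @param sample_ids character vector of length `n_samples`; defaults to
#'   `rownames(values)` or `S1..Sn`.
#'
#' @return An object of class `bin_matrix`: a list with elements `values`,
#'   `sample_ids`, `labels` (factor with levels OA, RA) and `bins`.
#' @examples
#' m <- bin_matrix(matrix(1:6, 3, 2), labels = c("OA", "OA", "RA"))
#' class_summary(m)
#' @export
bin_matrix <- function(values, labels, bins = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("bin", seq_len(ncol(values)))
  }
  if (is.null(bins)) {
    bins <- parse_bin_ids(colnames(values))
  }
  labels <- factor(as.character(labels), levels = c("OA", "RA"))
  obj <- structure(
    list(values = values, sample_ids = as.character(sample_ids),
         labels = labels, bins = bins),
    class = "bin_matrix"
  )
  validate_bin_matrix(obj)
  obj
}

#' @rdname bin_matrix
#' @param x a `bin_matrix`.
#' @export
validate_bin_matrix <- function(x) {
  stopifnot(inherits(x, "bin_matrix"))
  v <- x$values
  if (anyNA(v) || any(!is.finite(v))) {
    stop("bin_matrix values must be finite with no missing entries")
  }
  if (nrow(v) != length(x$sample_ids) || nrow(v) != length(x$labels)) {
    stop("sample_ids, labels and rows of values must agree in length")
  }
  if (ncol(v) != nrow(x$bins)) stop("bins metadata must have one row per column")
  if (anyNA(x$labels)) stop("labels must all be 'OA' or 'RA'")
  if (nlevels(droplevels(x$labels)) < 2) stop("both classes (OA and RA) must be present")
  if (anyDuplicated(x$bins$bin_id)) stop("bin_id must be unique")
  pp <- x$bins$ppm_center
  if (any(!is.na(pp) & !is.finite(pp))) stop("ppm_center must be finite or NA")
  invisible(x)
}

# "L-Glutamine [2.4482]" -> name + ppm; anything else keeps the id as name.
parse_bin_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.*?)\\s*\\[([-0-9.eE+]+)\\]\\s*$", ids))
  name <- vapply(seq_along(ids), function(i) {
    if (length(m[[i]]) == 3) m[[i]][2] else ids[i]
  }, character(1))
  ppm <- vapply(seq_along(ids), function(i) {
    if (length(m[[i]]) == 3) suppressWarnings(as.numeric(m[[i]][3])) else NA_real_
  }, numeric(1))
  data.frame(bin_id = ids, metabolite_name = name, ppm_center = ppm,
             stringsAsFactors = FALSE)
}

#' @rdname bin_matrix
#' @export
class_summary <- function(x) {
  stopifnot(inherits(x, "bin_matrix"))
  tab <- table(x$labels)
  list(n_OA = unname(tab[["OA"]]), n_RA = unname(tab[["RA"]]))
}

#' @export
print.bin_matrix <- function(x, ...) {
  cs <- class_summary(x)
  cat(sprintf("bin_matrix: %d samples (%d OA, %d RA) x %d bins\n",
              nrow(x$values), cs$n_OA, cs$n_RA, ncol(x$values)))
  invisible(x)
}

#' @export
dim.bin_matrix <- function(x) dim(x$values)

#' Subset the bins of a bin matrix
#'
#' @param x a `bin_matrix`.
#' @param bins integer, logical or character (bin_id) index of bins to keep.
#' @return a `bin_matrix` restricted to the selected bins.
#' @export
subset_bins <- function(x, bins) {
  stopifnot(inherits(x, "bin_matrix"))
  if (is.character(bins)) bins <- match(bins, x$bins$bin_id)
  if (anyNA(bins)) stop("unknown bin_id in subset")
  bin_matrix(x$values[, bins, drop = FALSE], labels = x$labels,
             bins = x$bins[bins, , drop = FALSE], sample_ids = x$sample_ids)
}

# 0/1 class code used everywhere downstream: OA = 0, RA = 1.
class_code <- function(labels) as.integer(labels == "RA")
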