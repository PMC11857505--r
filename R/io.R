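#' Read a labelled bin table
#'
#' Reads a delimited samples x bins table (rows = patients, columns =
#' metabolite bins, plus a label column) and returns a cleaned
#' [bin_matrix()]. Columns lacking sufficient information are dropped with a
#' message: any column containing a missing value, a non-numeric entry, or
#' with zero variance across samples.
#'
#' @param path path to a TSV/CSV file with a header row. The delimiter is
#'   auto-detected unless `sep` is given.
#' @param label_column name of the column holding the OA/RA diagnosis.
#' @param sep optional field separator passed to the reader.
#' @return a cleaned [bin_matrix()].
#' @seealso [write_bin_table()], [read_maf()]
#' @export
read_bin_table <- function(path, label_column = "label", sep = "auto") {
  if (!file.exists(path)) stop("cannot read file: ", path)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE, check.names = FALSE)
  if (!label_column %in% names(dt)) {
    stop("label column '", label_column, "' not found in ", path)
  }
  labels <- toupper(trimws(as.character(dt[[label_column]])))
  if (!all(labels %in% c("OA", "RA"))) {
    stop("label column must contain only OA/RA values")
  }
  sample_ids <- if ("sample_id" %in% names(dt)) {
    as.character(dt[["sample_id"]])
  } else {
    paste0("S", seq_len(nrow(dt)))
  }
  keep_meta <- setdiff(names(dt), c(label_column, "sample_id"))
  vals <- dt[keep_meta]

  dropped <- character(0)
  cols <- lapply(vals, function(col) {
    if (!is.numeric(col)) col <- suppressWarnings(as.numeric(as.character(col)))
    col
  })
  ok <- vapply(cols, function(col) {
    !anyNA(col) && all(is.finite(col)) && stats::var(col) > 0
  }, logical(1))
  dropped <- keep_meta[!ok]
  if (length(dropped)) {
    message("read_bin_table: dropped ", length(dropped),
            " column(s) lacking sufficient information: ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ..." else "")
  }
  if (!any(ok)) stop("no usable bin columns after cleaning")
  m <- do.call(cbind, cols[ok])
  colnames(m) <- keep_meta[ok]
  if (length(unique(labels)) < 2) stop("a class is absent after cleaning")
  bin_matrix(m, labels = labels, sample_ids = sample_ids)
}

#' Write a labelled bin table
#'
#' Writes a [bin_matrix()] as a TSV with `sample_id` and `label` columns
#' followed by one column per bin (named by `bin_id`). Values are written
#' with 15 significant digits so that a write/read round trip reproduces
#' them to within 1e-9 relative.
#'
#' @param matrix a `bin_matrix`.
#' @param path output file path.
#' @export
write_bin_table <- function(matrix, path) {
  validate_bin_matrix(matrix)
  df <- data.frame(sample_id = matrix$sample_ids,
                   label = as.character(matrix$labels),
                   stringsAsFactors = FALSE, check.names = FALSE)
  vals <- as.data.frame(matrix$values, check.names = FALSE)
  names(vals) <- matrix$bins$bin_id
  out <- cbind(df, vals)
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot write to path: ", path)
  })
  on.exit(close(con))
  utils::write.table(format(out, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a MetaboLights metabolite assignment file (MAF)
#'
#' MAF files are tab-separated with one row per metabolite bin and one
#' column per sample, alongside annotation columns. The table is transposed
#' into the samples x bins orientation used by the pipeline; the
#' `metabolite_identification` and `chemical_shift` columns populate the bin
#' metadata. Sample labels are not part of the MAF dialect and are supplied
#' separately.
#'
#' @param path path to a tab-separated MAF.
#' @param labels named character vector (or a function of sample id)
#'   mapping each sample column to "OA" or "RA".
#' @param sample_cols optional character vector naming the sample columns;
#'   by default every column not recognized as annotation is a sample.
#' @return a [bin_matrix()].
#' @export
read_maf <- function(path, labels, sample_cols = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, check.names = FALSE)
  annot <- c("database_identifier", "chemical_formula", "smiles", "inchi",
             "metabolite_identification", "chemical_shift", "multiplicity",
             "taxid", "species", "database", "database_version", "reliability",
             "uri", "search_engine", "search_engine_score",
             "smallmolecule_abundance_sub",
             "smallmolecule_abundance_stdev_sub",
             "smallmolecule_abundance_std_error_sub")
  if (is.null(sample_cols)) sample_cols <- setdiff(names(dt), annot)
  if (!length(sample_cols)) stop("no sample columns found in MAF")
  missing_cols <- setdiff(sample_cols, names(dt))
  if (length(missing_cols)) {
    stop("missing sample columns: ", paste(missing_cols, collapse = ", "))
  }
  met <- if ("metabolite_identification" %in% names(dt)) {
    as.character(dt[["metabolite_identification"]])
  } else {
    paste0("bin", seq_len(nrow(dt)))
  }
  ppm <- if ("chemical_shift" %in% names(dt)) {
    suppressWarnings(as.numeric(dt[["chemical_shift"]]))
  } else {
    rep(NA_real_, nrow(dt))
  }
  bin_id <- ifelse(is.na(ppm), met, sprintf("%s [%s]", met, ppm))
  if (anyDuplicated(bin_id)) {
    stop("duplicate bin identifiers in MAF: ",
         paste(unique(bin_id[duplicated(bin_id)]), collapse = ", "))
  }
  # vapply over MAF rows (bins) yields a samples x bins matrix directly
  m <- vapply(seq_len(nrow(dt)), function(i) {
    row <- suppressWarnings(as.numeric(unlist(dt[i, sample_cols])))
    if (anyNA(row)) {
      stop("non-numeric abundance in MAF row ", i, " (", bin_id[i], ")")
    }
    row
  }, numeric(length(sample_cols)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(sample_cols))
  dimnames(m) <- list(sample_cols, bin_id)
  if (is.function(labels)) labels <- vapply(sample_cols, labels, character(1))
  lab <- labels[sample_cols]
  if (anyNA(lab)) stop("labels missing for some sample columns")
  bins <- data.frame(bin_id = bin_id, metabolite_name = met,
                     ppm_center = ppm, stringsAsFactors = FALSE)
  bin_matrix(m, labels = lab, bins = bins, sample_ids = sample_cols)
}
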