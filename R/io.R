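#' Read a labelled sample-by-feature table
#'
#' Reads a delimited text table (comma for `.csv`, tab for `.tsv`/`.txt`/
#' `.tab`, or an explicit `delim`) with one label column and numeric feature
#' columns. Microarray-style matrices with genes in rows can be transposed on
#' the way in, in which case sample labels come from a designated row.
#'
#' @param path File to read.
#' @param label_column Name of the label column (default `"class"`); for
#'   `genes_in_rows = TRUE`, the name of the row (first-column value) holding
#'   the labels.
#' @param delim Field delimiter; `NULL` (default) auto-detects from the file
#'   extension.
#' @param genes_in_rows If `TRUE`, the table is features-in-rows (first
#'   column = feature name, remaining columns = samples) and is transposed.
#' @return A tibble with the label column first, then numeric features.
#' @export
read_labeled_table <- function(path, label_column = "class", delim = NULL,
                               genes_in_rows = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "lhda_error_io")
  }
  delim <- delim %||% .guess_delim(path)
  raw <- suppressMessages(readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = "c"),
    progress = FALSE))
  if (genes_in_rows) raw <- .transpose_gene_table(raw, label_column)
  if (!label_column %in% names(raw)) {
    abort(sprintf("label column '%s' not found (columns: %s).",
                  label_column, paste(head(names(raw), 8), collapse = ", ")),
          class = "lhda_error_schema")
  }
  feat_names <- setdiff(names(raw), label_column)
  if (anyDuplicated(feat_names)) {
    abort("duplicate feature names in header.", class = "lhda_error_schema")
  }
  out <- raw[label_column]
  for (nm in feat_names) {
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    bad <- which(is.na(v) & !is.na(raw[[nm]]) | is.na(raw[[nm]]))
    if (length(bad)) {
      abort(sprintf("non-numeric value '%s' at row %d, column '%s'.",
                    raw[[nm]][bad[1]], bad[1], nm),
            class = "lhda_error_parse")
    }
    out[[nm]] <- v
  }
  lab <- suppressWarnings(as.numeric(out[[label_column]]))
  if (!anyNA(lab)) out[[label_column]] <- lab
  tibble::as_tibble(out)
}

.guess_delim <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") "," else "\t"
}

.transpose_gene_table <- function(raw, label_column) {
  feat <- raw[[1]]
  mat <- t(as.matrix(raw[, -1, drop = FALSE]))
  colnames(mat) <- feat
  out <- tibble::as_tibble(as.data.frame(mat, stringsAsFactors = FALSE))
  if (!label_column %in% names(out)) {
    abort(sprintf("label row '%s' not found in the first column.",
                  label_column), class = "lhda_error_schema")
  }
  dplyr::relocate(out, dplyr::all_of(label_column))
}

#' Write a labelled table
#'
#' @param data Data frame (label column included) to write.
#' @param path Output file; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @return `path`, invisibly.
#' @export
write_labeled_table <- function(data, path) {
  if (tolower(tools::file_ext(path)) == "csv") {
    readr::write_csv(data, path)
  } else {
    readr::write_tsv(data, path)
  }
  invisible(path)
}

#' Write feature weights as a two-column TSV
#'
#' Columns `feature` and `weight`, sorted by descending weight with
#' alphabetical order among equal weights, written at full precision.
#'
#' @param w Numeric weight vector, or an `lhda_fit`.
#' @param feature_names Names matching `w` (taken from the fit or from
#'   `names(w)` when omitted).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_weights <- function(w, path, feature_names = NULL) {
  if (inherits(w, "lhda_fit")) {
    feature_names <- feature_names %||% w$dataset$feature_names
    w <- unname(w$w)
  }
  feature_names <- feature_names %||% names(w)
  if (is.null(feature_names) || length(feature_names) == 0) {
    abort("feature names are required to write weights.",
          class = "lhda_error_validation")
  }
  if (length(feature_names) != length(w)) {
    abort("feature names and weights differ in length.",
          class = "lhda_error_dimension")
  }
  o <- order(-w, feature_names)
  df <- tibble::tibble(feature = feature_names[o], weight = unname(w)[o])
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read feature weights written by [write_weights()]
#'
#' @param path TSV with columns `feature` and `weight`.
#' @return A named numeric vector.
#' @export
read_weights <- function(path) {
  df <- suppressMessages(readr::read_tsv(path, progress = FALSE,
                                         show_col_types = FALSE))
  setNames(df$weight, df$feature)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
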