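#' Assemble a labelled sample-by-feature dataset
#'
#' Converts a data frame with one label column (or a numeric matrix plus a
#' label vector) into the internal representation used by every fitting and
#' evaluation function: an `N x D` numeric feature matrix, integer class codes
#' `1..c` assigned by sorting the distinct original labels, and the retained
#' original labels for reporting predictions.
#'
#' @param data A data frame whose non-label columns are all numeric features,
#'   or a numeric matrix (then `labels` must be given).
#' @param label Column holding the class label (tidyselect semantics, default
#'   `class`). Ignored when `data` is a matrix.
#' @param labels Label vector, only when `data` is a matrix.
#'
#' @return An object of class `lhda_dataset`: a list with elements `x`
#'   (feature matrix), `y` (integer codes in `1..c`), `feature_names`,
#'   `class_labels` (sorted original labels) and `n`, `d`, `n_classes`.
#' @export
#' @examples
#' d <- blob_data(n_per_class = 5, n_classes = 2, seed = 1)
#' ds <- as_lhda_dataset(d)
#' ds$n_classes
as_lhda_dataset <- function(data, label = "class", labels = NULL) {
  if (inherits(data, "lhda_dataset")) return(data)
  if (is.matrix(data)) {
    if (is.null(labels)) {
      abort("`labels` must be supplied when `data` is a matrix.",
            class = "lhda_error_validation")
    }
    x <- data
    if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
    lab <- labels
  } else {
    data <- as.data.frame(data)
    loc <- tidyselect::eval_select(rlang::enquo(label), data)
    if (length(loc) != 1) {
      abort("`label` must select exactly one column.",
            class = "lhda_error_schema")
    }
    lab <- data[[loc]]
    feat <- data[, -loc, drop = FALSE]
    bad <- !vapply(feat, is.numeric, logical(1))
    if (any(bad)) {
      abort(paste0("non-numeric feature column(s): ",
                   paste(names(feat)[bad], collapse = ", ")),
            class = "lhda_error_validation")
    }
    x <- as.matrix(feat)
  }
  if (anyNA(x)) {
    abort("feature matrix contains missing values.",
          class = "lhda_error_validation")
  }
  if (length(lab) != nrow(x)) {
    abort("label length does not match the number of samples.",
          class = "lhda_error_dimension")
  }
  if (nrow(x) < 2 || ncol(x) < 1) {
    abort("need at least 2 samples and 1 feature.",
          class = "lhda_error_validation")
  }
  if (anyDuplicated(colnames(x))) {
    abort("duplicate feature names.", class = "lhda_error_schema")
  }
  if (is.factor(lab)) lab <- as.character(lab)
  class_labels <- sort(unique(lab))
  y <- match(lab, class_labels)
  structure(
    list(x = unname(x), y = y, feature_names = colnames(x),
         class_labels = class_labels,
         n = nrow(x), d = ncol(x), n_classes = length(class_labels)),
    class = "lhda_dataset")
}

#' @export
print.lhda_dataset <- function(x, ...) {
  cat(sprintf("<lhda_dataset: %d samples x %d features, %d classes (%s)>\n",
              x$n, x$d, x$n_classes,
              paste(x$class_labels, collapse = ", ")))
  invisible(x)
}

#' Dataset back to a tibble
#'
#' @param x An `lhda_dataset`.
#' @param label Name for the label column in the output.
#' @return A tibble with the label column first, then one column per feature.
#' @export
dataset_to_tibble <- function(x, label = "class") {
  x <- as_lhda_dataset(x)
  out <- tibble::as_tibble(as.data.frame(x$x))
  names(out) <- x$feature_names
  dplyr::bind_cols(tibble::tibble(!!label := x$class_labels[x$y]), out)
}

# class member indices, in ascending sample order
.class_members <- function(ds, class_code) which(ds$y == class_code)

# guard: every class needs at least `min_size` members
.check_class_sizes <- function(ds, min_size, context) {
  sizes <- tabulate(ds$y, nbins = ds$n_classes)
  small <- which(sizes < min_size)
  if (length(small)) {
    abort(sprintf(
      "%s: class(es) %s have fewer than %d members (sizes: %s).",
      context,
      paste(ds$class_labels[small], collapse = ", "), min_size,
      paste(sizes[small], collapse = ", ")),
      class = "lhda_error_insufficient_neighbors")
  }
  invisible(TRUE)
}
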