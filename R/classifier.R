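# prediction engine: per query, one local hyperplane per class (no
# exclusion -- queries are test samples); smallest distance wins, ties to the
# smallest class label
.predict_engine <- function(ds, Xnew, w, control) {
  .check_class_sizes(ds, control$k, "prediction")
  members <- lapply(seq_len(ds$n_classes), function(cc) .class_members(ds, cc))
  dmat <- .wl1_cross(Xnew, ds$x, w)
  n_new <- nrow(Xnew)
  dist <- matrix(NA_real_, n_new, ds$n_classes)
  Xt <- t(ds$x)
  for (i in seq_len(n_new)) {
    x <- Xnew[i, ]
    for (cc in seq_len(ds$n_classes)) {
      mem <- members[[cc]]
      nb <- mem[order(dmat[i, mem], mem)[seq_len(control$k)]]
      H <- Xt[, nb, drop = FALSE]
      s <- drop(H %*% .solve_alpha(x, H, w, control$solver_mode))
      dist[i, cc] <- sum(w * abs(x - s))
    }
  }
  list(pred = apply(dist, 1, which.min), dist = dist)
}

#' Classify new samples with the feature-weighted hyperplane rule
#'
#' For each query, builds one local hyperplane per training class in the
#' weighted metric and assigns the label whose hyperplane is closest
#' (\eqn{c^* = \arg\min_j d(x, LH_{c_j})}); distance ties go to the smallest
#' class label. Training samples are never excluded at test time.
#'
#' @param train Labelled training data (data frame or `lhda_dataset`).
#' @param new_data Data frame or matrix of query samples (feature columns
#'   matching the training features; a label column, if present, is ignored).
#' @param w Feature weight vector.
#' @param control An [lhda_control()].
#' @inheritParams as_lhda_dataset
#' @return A tibble with `.pred` (predicted labels, on the original label
#'   scale) and one `.dist_<class>` column of hyperplane distances per class.
#' @export
fhknn_predict <- function(train, new_data, w, control = lhda_control(),
                          label = "class") {
  ds <- as_lhda_dataset(train, label = {{ label }})
  .check_weights(w, ds$d)
  Xnew <- .coerce_query(new_data, ds)
  res <- .predict_engine(ds, Xnew, w, control)
  out <- tibble::tibble(.pred = ds$class_labels[res$pred])
  dn <- paste0(".dist_", ds$class_labels)
  for (j in seq_len(ds$n_classes)) out[[dn[j]]] <- res$dist[, j]
  out
}

.coerce_query <- function(new_data, ds) {
  if (is.matrix(new_data)) {
    X <- new_data
  } else {
    new_data <- as.data.frame(new_data)
    if (all(ds$feature_names %in% names(new_data))) {
      X <- as.matrix(new_data[, ds$feature_names, drop = FALSE])
    } else {
      num <- vapply(new_data, is.numeric, logical(1))
      X <- as.matrix(new_data[, num, drop = FALSE])
    }
  }
  if (ncol(X) != ds$d) {
    abort(sprintf("query has %d features, training data has %d.",
                  ncol(X), ds$d), class = "lhda_error_dimension")
  }
  unname(X)
}

#' @param object An `lhda_fit`.
#' @param new_data Data frame or matrix of samples to classify.
#' @param ... Unused.
#' @rdname lhda_fit
#' @export
predict.lhda_fit <- function(object, new_data, ...) {
  fhknn_predict(object$dataset, new_data, unname(object$w),
                control = object$control)
}

#' Selected feature subset from a weight vector
#'
#' Indices of features whose weight reaches the relative threshold
#' `tau * max(w)`; with `tau = 0`, all strictly positive weights. The cut is
#' scale-free: rescaling `w` by a positive constant changes nothing.
#'
#' @param w Nonnegative weight vector (or an `lhda_fit`).
#' @param tau Relative threshold in `[0, 1]` (default 0.01).
#' @return Sorted integer vector of feature indices.
#' @export
select_features <- function(w, tau = 0.01) {
  if (inherits(w, "lhda_fit")) w <- unname(w$w)
  stopifnot(tau >= 0, tau <= 1)
  if (any(w < 0)) {
    abort("weights must be nonnegative.", class = "lhda_error_validation")
  }
  if (all(w == 0)) {
    abort("all-zero weight vector has no selectable features.",
          class = "lhda_error_validation")
  }
  if (tau == 0) return(which(w > 0))
  which(w >= tau * max(w))
}
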