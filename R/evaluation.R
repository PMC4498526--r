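.new_cv_result <- function(scheme, ds, truth_code, pred_code, fold, seed,
                           control) {
  lev <- ds$class_labels
  truth <- factor(lev[truth_code], levels = lev)
  pred <- factor(lev[pred_code], levels = lev)
  cm <- table(truth = truth, predicted = pred)
  structure(
    list(scheme = scheme,
         predictions = tibble::tibble(
           row = seq_along(truth_code), truth = lev[truth_code],
           predicted = lev[pred_code], fold = fold,
           correct = truth_code == pred_code),
         accuracy = mean(truth_code == pred_code),
         confusion = cm, seed = seed, control = control,
         n = length(truth_code)),
    class = "lhda_cv")
}

#' @export
print.lhda_cv <- function(x, ...) {
  cat(sprintf("<lhda_cv: %s, %d samples, accuracy %.4f>\n",
              x$scheme, x$n, x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' @export
tidy.lhda_cv <- function(x, ...) x$predictions

#' @export
glance.lhda_cv <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, n = x$n, accuracy = x$accuracy,
                 seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}

#' @export
autoplot.lhda_cv <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac") +
    ggplot2::labs(title = sprintf("%s confusion matrix (accuracy %.3f)",
                                  object$scheme, object$accuracy)) +
    ggplot2::theme_minimal()
}

#' Leave-one-out cross-validation at fixed feature weights
#'
#' Each sample is predicted by the hyperplane rule built from the remaining
#' `N - 1` samples, with the supplied weights held fixed (mirroring the
#' protocol of learning weights once and then evaluating classifiers in the
#' weighted space).
#'
#' @param data Labelled data (data frame or `lhda_dataset`).
#' @param w Feature weight vector, or an `lhda_fit` whose weights are used.
#' @param control An [lhda_control()].
#' @inheritParams as_lhda_dataset
#' @return An object of class `lhda_cv`.
#' @export
lhda_loocv <- function(data, w, control = lhda_control(), label = "class") {
  ds <- as_lhda_dataset(data, label = {{ label }})
  if (inherits(w, "lhda_fit")) w <- unname(w$w)
  .check_weights(w, ds$d)
  .check_class_sizes(ds, control$k + 1L, "leave-one-out CV")
  members <- lapply(seq_len(ds$n_classes), function(cc) .class_members(ds, cc))
  dmat <- .wl1_cross(ds$x, ds$x, w)
  pred <- integer(ds$n)
  Xt <- t(ds$x)
  for (i in seq_len(ds$n)) {
    x <- Xt[, i]
    dist <- rep(Inf, ds$n_classes)
    for (cc in seq_len(ds$n_classes)) {
      mem <- members[[cc]]
      mem <- mem[mem != i]
      nb <- mem[order(dmat[i, mem], mem)[seq_len(control$k)]]
      H <- Xt[, nb, drop = FALSE]
      s <- drop(H %*% .solve_alpha(x, H, w, control$solver_mode))
      dist[cc] <- sum(w * abs(x - s))
    }
    pred[i] <- which.min(dist)
  }
  .new_cv_result("loocv", ds, ds$y, pred, fold = seq_len(ds$n), seed = NULL,
                 control = control)
}

# stratified fold assignment: within each class, shuffled members are dealt
# round-robin, so per-class fold sizes differ by at most one
.stratified_folds <- function(ds, folds, seed) {
  assign_fold <- function() {
    f <- integer(ds$n)
    for (cc in seq_len(ds$n_classes)) {
      mem <- .class_members(ds, cc)
      if (length(mem) < folds) {
        abort(sprintf(
          "class '%s' has %d member(s), fewer than %d folds.",
          ds$class_labels[cc], length(mem), folds),
          class = "lhda_error_stratification")
      }
      f[sample(mem)] <- rep_len(seq_len(folds), length(mem))
    }
    f
  }
  if (is.null(seed)) assign_fold() else withr::with_seed(seed, assign_fold())
}

#' Stratified k-fold cross-validation at fixed feature weights
#'
#' Folds are stratified by class (per-class sizes differ by at most one);
#' each fold is predicted by the hyperplane rule trained on the remaining
#' folds. Deterministic given `seed`.
#'
#' @inheritParams lhda_loocv
#' @param folds Number of folds (default 10).
#' @param seed Optional integer controlling the fold assignment.
#' @param stratify Stratify folds by class (default `TRUE`). With
#'   `stratify = FALSE` samples are dealt to folds regardless of class
#'   (sizes still differ by at most one); `folds = N` then degenerates to
#'   leave-one-out.
#' @return An object of class `lhda_cv`.
#' @export
lhda_kfold <- function(data, w, folds = 10, control = lhda_control(),
                       seed = NULL, stratify = TRUE, label = "class") {
  ds <- as_lhda_dataset(data, label = {{ label }})
  if (inherits(w, "lhda_fit")) w <- unname(w$w)
  .check_weights(w, ds$d)
  if (folds < 2) {
    abort("`folds` must be at least 2.", class = "lhda_error_validation")
  }
  fold <- if (stratify) {
    .stratified_folds(ds, folds, seed)
  } else {
    if (ds$n < folds) {
      abort("more folds than samples.", class = "lhda_error_stratification")
    }
    assign_plain <- function() {
      f <- integer(ds$n)
      f[sample(ds$n)] <- rep_len(seq_len(folds), ds$n)
      f
    }
    if (is.null(seed)) assign_plain() else withr::with_seed(seed, assign_plain())
  }
  pred <- integer(ds$n)
  for (f in seq_len(folds)) {
    test <- which(fold == f)
    train <- which(fold != f)
    sub <- as_lhda_dataset(ds$x[train, , drop = FALSE],
                           labels = ds$class_labels[ds$y[train]])
    res <- .predict_engine(sub, ds$x[test, , drop = FALSE], w, control)
    pred[test] <- match(sub$class_labels[res$pred], ds$class_labels)
  }
  .new_cv_result(sprintf("%d-fold", folds), ds, ds$y, pred, fold = fold,
                 seed = seed, control = control)
}

#' Nested leave-one-out loop with per-split weight learning
#'
#' The leakage-free protocol: each sample is removed, the entire weight
#' learning ([lhda_fit()]) is re-run on the remaining samples, and the
#' held-out sample is predicted in the split's own weighted space. Nothing
#' about the held-out sample touches weight learning.
#'
#' @inheritParams lhda_loocv
#' @param keep_weights If `TRUE`, attach the matrix of per-split learned
#'   weights (`N x D`) as element `weights`.
#' @return An object of class `lhda_cv` (with element `weights` when
#'   requested).
#' @export
lhda_inner_loocv <- function(data, control = lhda_control(),
                             keep_weights = FALSE, label = "class") {
  ds <- as_lhda_dataset(data, label = {{ label }})
  .check_class_sizes(ds, control$k + 2L, "nested leave-one-out")
  pred <- integer(ds$n)
  W <- if (keep_weights) matrix(NA_real_, ds$n, ds$d)
  for (i in seq_len(ds$n)) {
    sub <- as_lhda_dataset(ds$x[-i, , drop = FALSE],
                           labels = ds$class_labels[ds$y[-i]])
    res <- .fit_engine(sub, control)
    if (keep_weights) W[i, ] <- res$w
    out <- .predict_engine(sub, ds$x[i, , drop = FALSE], res$w, control)
    pred[i] <- match(sub$class_labels[out$pred], ds$class_labels)
  }
  cv <- .new_cv_result("inner-loocv", ds, ds$y, pred, fold = seq_len(ds$n),
                       seed = NULL, control = control)
  if (keep_weights) cv$weights <- W
  cv
}

#' Two-sample t-test feature prefilter
#'
#' The standard microarray preprocessing step: keeps features whose pooled
#' -variance (Student) two-sample t-test p-value is below `alpha`. Features
#' with zero variance in both classes and equal means have no defined
#' statistic and are dropped. Two classes only.
#'
#' @param data Labelled data (data frame or `lhda_dataset`).
#' @param alpha Significance level (default 0.05).
#' @param var_equal If `TRUE` (default), the classic pooled-variance test;
#'   otherwise Welch.
#' @inheritParams as_lhda_dataset
#' @return An object of class `lhda_prefilter`: list with `data` (filtered
#'   tibble, label column first), `kept` (original feature indices, in
#'   order) and `stats` (per-feature tibble of statistics and p-values).
#' @export
ttest_prefilter <- function(data, alpha = 0.05, var_equal = TRUE,
                            label = "class") {
  ds <- as_lhda_dataset(data, label = {{ label }})
  if (ds$n_classes != 2) {
    abort("the t-test prefilter supports exactly two classes.",
          class = "lhda_error_unsupported")
  }
  g1 <- ds$x[ds$y == 1, , drop = FALSE]
  g2 <- ds$x[ds$y == 2, , drop = FALSE]
  n1 <- nrow(g1); n2 <- nrow(g2)
  if (n1 < 2 || n2 < 2) {
    abort("each class needs at least two samples for the t-test.",
          class = "lhda_error_validation")
  }
  m1 <- colMeans(g1); m2 <- colMeans(g2)
  v1 <- apply(g1, 2, stats::var); v2 <- apply(g2, 2, stats::var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, ds$d)
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  delta <- m1 - m2
  tstat <- ifelse(se == 0, ifelse(delta == 0, NA_real_, Inf * sign(delta)),
                  delta / se)
  p <- ifelse(is.na(tstat), NA_real_,
              ifelse(is.infinite(tstat), 0, 2 * pt(-abs(tstat), df)))
  keep <- !is.na(p) & p < alpha
  stats_tbl <- tibble::tibble(feature = ds$feature_names,
                              statistic = tstat, p_value = p, kept = keep)
  kept_idx <- which(keep)
  filtered <- dataset_to_tibble(
    as_lhda_dataset(ds$x[, kept_idx, drop = FALSE] |>
                      `colnames<-`(ds$feature_names[kept_idx]),
                    labels = ds$class_labels[ds$y]))
  structure(list(data = filtered, kept = kept_idx, stats = stats_tbl,
                 alpha = alpha, var_equal = var_equal),
            class = "lhda_prefilter")
}

#' @export
print.lhda_prefilter <- function(x, ...) {
  cat(sprintf("<lhda_prefilter: kept %d of %d features at alpha = %g>\n",
              length(x$kept), nrow(x$stats), x$alpha))
  invisible(x)
}

#' @export
tidy.lhda_prefilter <- function(x, ...) x$stats

#' Write a cross-validation result as JSON
#'
#' Emits scheme, accuracy, confusion matrix, seed and the configuration
#' snapshot as a single JSON object.
#'
#' @param cv An `lhda_cv`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cv_json <- function(cv, path) {
  obj <- list(scheme = cv$scheme, n = cv$n, accuracy = cv$accuracy,
              confusion = as.matrix(unclass(cv$confusion)),
              class_labels = rownames(cv$confusion),
              seed = cv$seed, control = unclass(cv$control))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write per-sample cross-validation predictions as TSV
#'
#' @inheritParams write_cv_json
#' @export
write_cv_predictions <- function(cv, path) {
  readr::write_tsv(cv$predictions, path)
  invisible(path)
}
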