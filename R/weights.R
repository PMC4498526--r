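#' Sigmoid-smoothed step function and its derivative
#'
#' The 0/1 leave-one-out error indicator \eqn{S(R) = [R \ge 1]} is smoothed to
#' \eqn{S_\beta(z) = 1 / (1 + e^{\beta(1 - z)})} so that the margin objective
#' becomes differentiable. `sigmoid_step(1, beta)` is exactly 0.5 for every
#' slope, and the derivative at 1 is `beta / 4`.
#'
#' @param z Margin ratio value(s).
#' @param beta Positive slope.
#' @return `sigmoid_step`: values in (0, 1); `sigmoid_step_deriv`: the
#'   derivative \eqn{\beta e^{\beta(1-z)} / (1 + e^{\beta(1-z)})^2}.
#' @export
sigmoid_step <- function(z, beta) {
  stopifnot(beta > 0)
  plogis(beta * (z - 1))
}

#' @rdname sigmoid_step
#' @export
sigmoid_step_deriv <- function(z, beta) {
  stopifnot(beta > 0)
  beta * dlogis(beta * (z - 1))
}

# margin ratio with the degenerate-case conventions:
# d_NM = 0 and d_NH > 0 -> ratio_cap; both zero -> 1
.ratio <- function(dNH, dNM, cap) {
  ifelse(dNM == 0, ifelse(dNH == 0, 1, cap), dNH / dNM)
}

# One pass over all samples at fixed w: leave-one-out nearest-hit and
# nearest-miss hyperplanes, their distances and |x - s| matrices.
.margin_pass <- function(ds, w, control) {
  N <- ds$n
  D <- ds$d
  k <- control$k
  mode <- control$solver_mode
  members <- lapply(seq_len(ds$n_classes), function(cc) .class_members(ds, cc))
  dmat <- .wl1_cross(ds$x, ds$x, w)
  dNH <- dNM <- numeric(N)
  ANH <- ANM <- matrix(0, N, D)
  Xt <- t(ds$x)                             # D x N, for cheap column grabs
  for (i in seq_len(N)) {
    x <- Xt[, i]
    own <- members[[ds$y[i]]]
    own <- own[own != i]
    if (length(own) < k) {
      abort(sprintf(
        "class '%s' has %d other member(s); leave-one-out hyperplanes need k = %d.",
        ds$class_labels[ds$y[i]], length(own), k),
        class = "lhda_error_insufficient_neighbors")
    }
    nb <- own[order(dmat[i, own], own)[seq_len(k)]]
    H <- Xt[, nb, drop = FALSE]
    s <- drop(H %*% .solve_alpha(x, H, w, mode))
    ANH[i, ] <- abs(x - s)
    dNH[i] <- sum(w * ANH[i, ])
    best <- Inf
    for (cc in seq_len(ds$n_classes)) {
      if (cc == ds$y[i]) next
      oth <- members[[cc]]
      if (length(oth) < k) {
        abort(sprintf(
          "class '%s' has %d member(s); nearest-miss hyperplanes need k = %d.",
          ds$class_labels[cc], length(oth), k),
          class = "lhda_error_insufficient_neighbors")
      }
      nb2 <- oth[order(dmat[i, oth], oth)[seq_len(k)]]
      H2 <- Xt[, nb2, drop = FALSE]
      s2 <- drop(H2 %*% .solve_alpha(x, H2, w, mode))
      d2 <- sum(w * abs(x - s2))
      if (d2 < best) {
        best <- d2
        ANM[i, ] <- abs(x - s2)
        dNM[i] <- d2
      }
    }
  }
  list(dNH = dNH, dNM = dNM, ANH = ANH, ANM = ANM)
}

#' Leave-one-out margin ratio of one training sample
#'
#' Builds the nearest-hit hyperplane (the sample's own class, the sample
#' itself excluded) and the nearest-miss hyperplane (the closest foreign
#' class) and returns their distance ratio
#' \eqn{R = d(x, NH) / d(x, NM)}. A ratio below 1 means the sample would be
#' correctly classified by the hyperplane rule. If the nearest-miss distance
#' is zero while the hit distance is positive, `R` is `control$ratio_cap`; if
#' both distances are zero, `R = 1`.
#'
#' @param sample_index Row index of the training sample.
#' @param data Labelled data (data frame or `lhda_dataset`).
#' @param w Feature weight vector.
#' @param control An [lhda_control()].
#' @inheritParams as_lhda_dataset
#' @return A list with elements `ratio`, `NH` and `NM` (both
#'   `local_hyperplane` objects).
#' @export
margin_ratio <- function(sample_index, data, w, control = lhda_control(),
                         label = "class") {
  ds <- as_lhda_dataset(data, label = {{ label }})
  .check_weights(w, ds$d)
  i <- as.integer(sample_index)
  stopifnot(i >= 1, i <= ds$n)
  own_label <- ds$class_labels[ds$y[i]]
  NH <- local_hyperplane(ds$x[i, ], ds, own_label, control$k, w,
                         mode = control$solver_mode, exclude_index = i)
  NM <- NULL
  for (cc in seq_len(ds$n_classes)) {
    if (cc == ds$y[i]) next
    cand <- local_hyperplane(ds$x[i, ], ds, ds$class_labels[cc], control$k, w,
                             mode = control$solver_mode)
    if (is.null(NM) || cand$distance < NM$distance) NM <- cand
  }
  list(ratio = .ratio(NH$distance, NM$distance, control$ratio_cap),
       NH = NH, NM = NM)
}

#' Per-sample margin terms at fixed weights
#'
#' Computes, for every training sample under the current weights, the
#' leave-one-out nearest-hit and nearest-miss hyperplanes, margin ratios
#' \eqn{R_i}, the sigmoid factors \eqn{\gamma_i = S'_\beta(R_i) R_i} and the
#' per-feature direction vectors
#' \eqn{g_i = |x_i - s_{NH}| / d_{NH} - |x_i - s_{NM}| / d_{NM}}
#' entering the gradient of the penalised objective.
#'
#' @inheritParams margin_ratio
#' @return An object of class `lhda_margin_terms`: list with `ratio`,
#'   `gamma` (length-N vectors), `g` (N x D matrix), `d_nh`, `d_nm`, and the
#'   absolute-residual matrices `a_nh`, `a_nm`.
#' @export
margin_terms <- function(data, w, control = lhda_control(), label = "class") {
  ds <- as_lhda_dataset(data, label = {{ label }})
  .check_weights(w, ds$d)
  mp <- .margin_pass(ds, w, control)
  R <- .ratio(mp$dNH, mp$dNM, control$ratio_cap)
  gamma <- sigmoid_step_deriv(R, control$beta) * R
  # zero-distance hyperplanes contribute no direction for that term
  G <- mp$ANH / ifelse(mp$dNH == 0, Inf, mp$dNH) -
       mp$ANM / ifelse(mp$dNM == 0, Inf, mp$dNM)
  structure(list(ratio = R, gamma = gamma, g = G,
                 d_nh = mp$dNH, d_nm = mp$dNM,
                 a_nh = mp$ANH, a_nm = mp$ANM),
            class = "lhda_margin_terms")
}

#' @export
print.lhda_margin_terms <- function(x, ...) {
  cat(sprintf("<lhda_margin_terms: %d samples, mean ratio %.4f>\n",
              length(x$ratio), mean(x$ratio)))
  invisible(x)
}

#' Penalised leave-one-out margin objective
#'
#' Evaluates \eqn{J(v) = N^{-1} \sum_i S_\beta(R_i) + \lambda \|v\|_2^2}
#' through the square-root parameterisation `w = v^2` (so the l1 penalty on
#' `w` is the smooth squared l2 norm of `v`). All margin ratios use
#' leave-one-out nearest-hit semantics.
#'
#' @param data Labelled data (data frame or `lhda_dataset`).
#' @param v Square-root weight vector (`w = v^2`); must not be all zero.
#' @param control An [lhda_control()].
#' @inheritParams as_lhda_dataset
#' @return The scalar objective value.
#' @export
penalized_objective <- function(data, v, control = lhda_control(),
                                label = "class") {
  ds <- as_lhda_dataset(data, label = {{ label }})
  w <- v * v
  .check_weights(w, ds$d)
  mp <- .margin_pass(ds, w, control)
  R <- .ratio(mp$dNH, mp$dNM, control$ratio_cap)
  mean(sigmoid_step(R, control$beta)) + control$lambda * sum(w)
}

#' Gradient of the penalised objective in the square-root parameterisation
#'
#' With hyperplanes and spanning coefficients frozen at the current weights
#' (the EM-like alternation), the gradient is the Hadamard product
#' \eqn{\partial J / \partial v =
#'   (2\lambda \mathbf{1} + (2/N) \Upsilon^T G) \otimes v}
#' with \eqn{\Upsilon^T G = \sum_i \gamma_i g_i}. Components with `v_j = 0`
#' are exactly zero.
#'
#' @inheritParams penalized_objective
#' @param terms Optional precomputed [margin_terms()] at the same `v`.
#' @return Length-D numeric gradient.
#' @export
objective_gradient <- function(data, v, control = lhda_control(),
                               terms = NULL, label = "class") {
  ds <- as_lhda_dataset(data, label = {{ label }})
  if (is.null(terms)) terms <- margin_terms(ds, v * v, control)
  ug <- colSums(terms$gamma * terms$g)
  (2 * control$lambda + (2 / ds$n) * ug) * v
}

# frozen-surrogate objective: hyperplane projections held fixed, distances
# re-weighted by the candidate w
.frozen_objective <- function(vv, mp, control) {
  ww <- vv * vv
  dh <- drop(mp$ANH %*% ww)
  dm <- drop(mp$ANM %*% ww)
  mean(sigmoid_step(.ratio(dh, dm, control$ratio_cap), control$beta)) +
    control$lambda * sum(ww)
}

.fit_engine <- function(ds, control) {
  .check_class_sizes(ds, control$k + 1L, "weight learning")
  if (ds$n_classes < 2) {
    abort("weight learning needs at least two classes.",
          class = "lhda_error_validation")
  }
  N <- ds$n
  D <- ds$d
  v <- rep(1 / sqrt(D), D)               # uniform w summing to 1
  mp <- .margin_pass(ds, v * v, control)
  R <- .ratio(mp$dNH, mp$dNM, control$ratio_cap)
  J <- mean(sigmoid_step(R, control$beta)) + control$lambda * sum(v * v)
  it_rows <- list()
  w_path <- if (control$keep_weight_path) list(v * v) else NULL
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(control$max_iter)) {
    gamma <- sigmoid_step_deriv(R, control$beta) * R
    G <- mp$ANH / ifelse(mp$dNH == 0, Inf, mp$dNH) -
         mp$ANM / ifelse(mp$dNM == 0, Inf, mp$dNM)
    grad <- (2 * control$lambda + (2 / N) * colSums(gamma * G)) * v
    if (all(grad == 0)) { converged <- TRUE; break }
    eta <- control$eta
    vn <- v
    Jf <- J
    accepted <- FALSE
    for (h in 0:control$max_halvings) {
      cand <- v - eta * grad
      Jc <- .frozen_objective(cand, mp, control)
      if (Jc <= J + 1e-12) { vn <- cand; Jf <- Jc; accepted <- TRUE; break }
      eta <- eta / 2
    }
    if (!accepted) { converged <- TRUE; break }
    mpn <- .margin_pass(ds, vn * vn, control)
    Rn <- .ratio(mpn$dNH, mpn$dNM, control$ratio_cap)
    Jn <- mean(sigmoid_step(Rn, control$beta)) + control$lambda * sum(vn * vn)
    # profile change: classification is invariant to the scale of w, and the
    # l1 penalty shrinks that scale indefinitely, so convergence is judged on
    # the normalised weight profile
    wo <- v * v
    wn <- vn * vn
    dw <- sum(abs(wn / sum(wn) - wo / sum(wo)))
    it_rows[[it]] <- c(iteration = it, objective = Jn, objective_frozen = Jf,
                       step_size = eta, delta_w = dw)
    if (control$keep_weight_path) w_path[[it + 1L]] <- vn * vn
    v <- vn; mp <- mpn; R <- Rn; J <- Jn
    iterations <- it
    if (dw < control$tol) { converged <- TRUE; break }
  }
  trace <- if (length(it_rows)) {
    tibble::as_tibble(do.call(rbind, it_rows))
  } else {
    tibble::tibble(iteration = numeric(), objective = numeric(),
                   objective_frozen = numeric(), step_size = numeric(),
                   delta_w = numeric())
  }
  list(v = v, w = v * v, trace = trace, weight_path = w_path,
       converged = converged, iterations = iterations, final_objective = J)
}

#' Learn feature weights by penalised leave-one-out margin descent
#'
#' The core fitting routine. Starting from uniform weights
#' (`w_j = 1/D`, honouring the sum-to-one convention at initialisation), it
#' alternates, EM-style: (a) rebuild every sample's leave-one-out nearest-hit
#' and nearest-miss hyperplanes under the current weighted metric; (b) take a
#' gradient step on `v` (`w = v^2`), backtracking (halving the step) until the
#' objective with hyperplanes frozen does not increase. Iteration stops when
#' the relative l1 change of `w` falls below `control$tol` or after
#' `control$max_iter` iterations. Nonnegativity of `w` is structural
#' (`w = v^2`), never enforced by clipping.
#'
#' @param data A data frame with one label column, or an `lhda_dataset`.
#' @param label Label column (tidyselect), default `class`.
#' @param control An [lhda_control()].
#' @param tau Relative threshold defining the selected feature subset
#'   (`w_j >= tau * max(w)`), stored on the fitted object.
#' @return An object of class `lhda_fit` with elements `w`, `v`, `trace`
#'   (per-iteration tibble), `control`, `dataset`, `selected`
#'   (feature indices), `converged`, `iterations`. Supports [tidy()],
#'   [glance()], [autoplot()] and [predict()].
#' @export
#' @examples
#' d <- blob_data(n_per_class = 8, n_classes = 2, informative_dims = 1,
#'                noise_dim = 3, separation = 6, seed = 1)
#' fit <- lhda_fit(d, control = lhda_control(k = 2, max_iter = 10))
#' tidy(fit)
lhda_fit <- function(data, label = "class", control = lhda_control(),
                     tau = 0.01) {
  ds <- as_lhda_dataset(data, label = {{ label }})
  res <- .fit_engine(ds, control)
  structure(
    list(w = setNames(res$w, ds$feature_names), v = res$v,
         trace = res$trace, weight_path = res$weight_path,
         control = control, dataset = ds, tau = tau,
         selected = select_features(res$w, tau),
         converged = res$converged, iterations = res$iterations,
         final_objective = res$final_objective),
    class = "lhda_fit")
}

#' @export
print.lhda_fit <- function(x, ...) {
  cat(sprintf(
    "<lhda_fit: %d features, %d classes, %d iterations (%s), %d selected at tau = %g>\n",
    x$dataset$d, x$dataset$n_classes, x$iterations,
    if (x$converged) "converged" else "max_iter reached",
    length(x$selected), x$tau))
  cat(sprintf("  final objective: %.6f\n", x$final_objective))
  invisible(x)
}

#' @export
tidy.lhda_fit <- function(x, ...) {
  tibble::tibble(
    feature = x$dataset$feature_names,
    weight = unname(x$w),
    weight_norm = unname(x$w) / sum(x$w),
    selected = seq_along(x$w) %in% x$selected)
}

#' @export
glance.lhda_fit <- function(x, ...) {
  tibble::tibble(
    n = x$dataset$n, n_features = x$dataset$d,
    n_classes = x$dataset$n_classes,
    iterations = x$iterations, converged = x$converged,
    objective = x$final_objective,
    n_selected = length(x$selected),
    lambda = x$control$lambda, beta = x$control$beta, k = x$control$k)
}

#' @export
autoplot.lhda_fit <- function(object, ...) {
  td <- tidy(object)
  td$index <- seq_len(nrow(td))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$index, y = .data$weight,
                                   fill = .data$selected)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "#2166ac")) +
    ggplot2::labs(x = "feature index", y = "weight",
                  title = "Learned feature-weight profile") +
    ggplot2::theme_minimal()
}
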