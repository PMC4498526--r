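#' Nearest neighbours of a point within one class
#'
#' Finds the `k` samples of a given class with the smallest feature-weighted
#' Manhattan distance to `x`. Ties are broken by ascending sample index so the
#' result is deterministic; an optional index (the query itself during
#' leave-one-out training) can be excluded from the candidate pool.
#'
#' @param x Query point (length-D numeric).
#' @param data Labelled data (data frame with a label column, or
#'   `lhda_dataset`).
#' @param class_label Class whose members are searched (an original label).
#' @param k Number of neighbours.
#' @param w Feature weight vector.
#' @param exclude_index Optional row index never returned.
#' @inheritParams as_lhda_dataset
#' @return Integer vector of `k` row indices into `data`.
#' @export
class_neighbors <- function(x, data, class_label, k, w,
                            exclude_index = NULL, label = "class") {
  ds <- as_lhda_dataset(data, label = {{ label }})
  code <- match(class_label, ds$class_labels)
  if (is.na(code)) {
    abort(sprintf("class '%s' not present in the data.", class_label),
          class = "lhda_error_validation")
  }
  .check_weights(w, ds$d)
  .neighbors_engine(x, ds$x, .class_members(ds, code), k, w,
                    exclude_index = exclude_index,
                    class_name = as.character(class_label))
}

# candidates: ascending sample indices of one class
.neighbors_engine <- function(x, X, candidates, k, w, exclude_index = NULL,
                              class_name = "?") {
  if (!is.null(exclude_index)) candidates <- candidates[candidates != exclude_index]
  if (k < 1 || length(candidates) < k) {
    abort(sprintf(
      "class '%s' has %d eligible sample(s) but k = %d neighbours were requested.",
      class_name, length(candidates), k),
      class = "lhda_error_insufficient_neighbors")
  }
  d <- .wl1_to_point(X[candidates, , drop = FALSE], x, w)
  candidates[order(d, candidates)[seq_len(k)]]
}

#' Spanning coefficients of a local hyperplane
#'
#' Solves for the simplex-constrained coefficients \eqn{\alpha} combining the
#' `k` neighbour columns of `H` into the hyperplane point closest to the
#' query. `mode = "exact"` minimises the true weighted-L1 objective
#' \eqn{w^T |x - H\alpha|} over the probability simplex (a small linear
#' program); `mode = "surrogate"` minimises the linearised upper bound
#' \eqn{\alpha^T z} with \eqn{z_i = w^T|x - h_i|}, whose optimum is the vertex
#' at the nearest single neighbour (ties split uniformly).
#'
#' The exact solve reduces the problem to an affine least-absolute-deviations
#' fit (Barrodale–Roberts, via \pkg{quantreg}); when the affine optimum falls
#' outside the simplex, convexity places the constrained optimum on a facet,
#' which is searched recursively down to edges solved in closed form by
#' weighted medians.
#'
#' @param x Query point (length-D numeric).
#' @param H `D x k` matrix whose columns are the neighbours.
#' @param w Feature weight vector (length D, nonnegative).
#' @param mode `"exact"` or `"surrogate"`.
#' @return Numeric length-`k` vector on the probability simplex.
#' @export
#' @examples
#' H <- cbind(c(0, 0), c(1, 0), c(0, 1))
#' spanning_coefficients(c(1, 0), H, c(1, 1))   # picks the matching vertex
spanning_coefficients <- function(x, H, w, mode = c("exact", "surrogate")) {
  mode <- match.arg(mode)
  if (!is.matrix(H)) H <- as.matrix(H)
  if (length(x) != nrow(H) || length(w) != nrow(H)) {
    abort("`x`, `w` and the rows of `H` must agree in length.",
          class = "lhda_error_dimension")
  }
  .check_weights(w, nrow(H))
  alpha <- .solve_alpha(as.numeric(x), H, as.numeric(w), mode)
  if (abs(sum(alpha) - 1) > 1e-9 || any(alpha < -1e-9)) {
    abort("spanning-coefficient solve returned an infeasible simplex point.",
          class = "lhda_error_optimization")
  }
  alpha
}

.alpha_objective <- function(alpha, x, H, w) sum(w * abs(x - drop(H %*% alpha)))

# exact 1-D edge solve: min over t in [0,1] of sum_j w_j |a_j - t b_j|,
# by the weighted median of the breakpoints a_j/b_j with masses w_j|b_j|
.wmedian_segment <- function(a, b, w) {
  nz <- b != 0 & w > 0
  if (!any(nz)) return(0)
  tj <- a[nz] / b[nz]
  u <- w[nz] * abs(b[nz])
  o <- order(tj)
  tj <- tj[o]
  cu <- cumsum(u[o])
  t <- tj[which(cu >= cu[length(cu)] / 2)[1]]
  min(max(t, 0), 1)
}

.lhda_env <- new.env(parent = emptyenv())

# minimal weighted-LAD fit: the Barrodale-Roberts simplex routine from
# quantreg, called directly (its wrapper re-runs a QR rank check and CI
# bookkeeping on every call, which dominates at our call rates); returns NULL
# on a premature exit so the caller can fall back to the facet search
.br_fit <- function(x, y) {
  sym <- .lhda_env$rqbr
  if (is.null(sym)) {
    sym <- tryCatch(getNativeSymbolInfo("rqbr", PACKAGE = "quantreg"),
                    error = function(e) NULL)
    if (is.null(sym)) sym <- NA
    .lhda_env$rqbr <- sym
  }
  p <- ncol(x)
  n <- nrow(x)
  if (!is.list(sym) && is.na(sym[1])) {
    fit <- tryCatch(
      suppressWarnings(quantreg::rq.fit.br(x, y, tau = 0.5)),
      error = function(e) NULL)
    return(if (is.null(fit)) NULL else unname(fit$coefficients))
  }
  z <- .Fortran(sym, as.integer(n), as.integer(p), as.integer(n + 5L),
                as.integer(p + 3L), as.integer(p + 4L), as.double(x),
                as.double(y), as.double(0.5),
                as.double(.Machine$double.eps^(2 / 3)),
                flag = as.integer(1), coef = double(p), resid = double(n),
                integer(n), double((n + 5) * (p + 4)), double(n),
                as.integer(2), as.integer(2), sol = double((p + 3) * 2),
                dsol = double(n * 2), lsol = as.integer(0),
                h = integer(p * 2), qn = double(p), cutoff = as.double(0),
                ci = double(4 * p), tnmat = double(4 * p),
                as.double(.Machine$double.xmax), as.logical(FALSE))
  if (z$flag == 2L) return(NULL)
  z$coef
}

# exact minimiser of w^T |x - H alpha| over the simplex
.solve_alpha_exact <- function(x, H, w) {
  k <- ncol(H)
  if (k == 1) return(1)
  if (k == 2) {
    t <- .wmedian_segment(x - H[, 2], H[, 1] - H[, 2], w)
    return(c(t, 1 - t))
  }
  # affine reduction: alpha_k = 1 - sum(beta); weighted LAD on scaled rows
  B <- H[, -k, drop = FALSE] - H[, k]
  r0 <- x - H[, k]
  keep <- w > 0
  cand <- list()
  if (sum(keep) >= k - 1) {
    sw <- w[keep]
    beta <- .br_fit(B[keep, , drop = FALSE] * sw, r0[keep] * sw)
    if (!is.null(beta) && !anyNA(beta) && all(beta >= -1e-9) &&
        sum(beta) <= 1 + 1e-9) {
      al <- pmax(c(beta, 1 - sum(beta)), 0)
      cand <- list(al / sum(al))
    }
  }
  if (length(cand) == 1) {
    # cheap optimality guard: an exact solve can never lose to a vertex
    fv <- min(.wl1_to_point(t(H), x, w))
    if (.alpha_objective(cand[[1]], x, H, w) > fv + 1e-9) cand <- list()
  }
  if (length(cand) == 0) {
    # affine optimum infeasible (or cheap enough to verify): search facets;
    # for a convex objective the constrained optimum then lies on one
    for (i in seq_len(k)) {
      sub <- .solve_alpha_exact(x, H[, -i, drop = FALSE], w)
      cand <- c(cand, list(append(sub, 0, after = i - 1)))
    }
  }
  vals <- vapply(cand, .alpha_objective, numeric(1), x = x, H = H, w = w)
  cand[[which.min(vals)]]
}

.solve_alpha_surrogate <- function(x, H, w) {
  z <- .wl1_to_point(t(H), x, w)
  tied <- z <= min(z) + 1e-12 * max(1, abs(min(z)))
  as.numeric(tied) / sum(tied)
}

.solve_alpha <- function(x, H, w, mode) {
  k <- ncol(H)
  if (k == 1) return(1)
  alpha <- if (mode == "surrogate") .solve_alpha_surrogate(x, H, w)
           else .solve_alpha_exact(x, H, w)
  # absorb solver round-off: clip to [0,1] and renormalise
  alpha <- pmin(pmax(alpha, 0), 1)
  alpha / sum(alpha)
}

#' Local hyperplane of one class for a query point
#'
#' Composes the per-class neighbour search with the spanning-coefficient
#' solve: the returned object carries the neighbour matrix `H`, the simplex
#' coefficients `alpha`, the projection point `s = H alpha` and the weighted
#' Manhattan distance from the query to `s`.
#'
#' @inheritParams class_neighbors
#' @inheritParams spanning_coefficients
#' @return An object of class `local_hyperplane`.
#' @export
local_hyperplane <- function(x, data, class_label, k, w,
                             mode = c("exact", "surrogate"),
                             exclude_index = NULL, label = "class") {
  mode <- match.arg(mode)
  ds <- as_lhda_dataset(data, label = {{ label }})
  .check_weights(w, ds$d)
  idx <- class_neighbors(x, ds, class_label, k, w,
                         exclude_index = exclude_index)
  .hyperplane_engine(as.numeric(x), ds, idx, class_label, w, mode)
}

.hyperplane_engine <- function(x, ds, idx, class_label, w, mode) {
  H <- t(ds$x[idx, , drop = FALSE])          # D x k
  alpha <- .solve_alpha(x, H, w, mode)
  s <- drop(H %*% alpha)
  structure(
    list(neighbor_matrix = H, neighbor_indices = idx,
         class_label = class_label, alpha = alpha, projection = s,
         distance = sum(w * abs(x - s))),
    class = "local_hyperplane")
}

#' @export
print.local_hyperplane <- function(x, ...) {
  cat(sprintf("<local_hyperplane: class %s, k = %d, distance = %.6g>\n",
              x$class_label, length(x$alpha), x$distance))
  invisible(x)
}
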