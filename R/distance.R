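#' Feature-weighted Manhattan distance
#'
#' The metric underlying the whole method:
#' \eqn{d(p, q) = \sum_j w_j |p_j - q_j|} with nonnegative per-feature
#' weights. Zero-weight features are ignored; the distance is zero iff the two
#' points agree on every positively weighted feature.
#'
#' @param p,q Numeric vectors of equal length.
#' @param w Nonnegative weight vector of the same length.
#' @return A single nonnegative number.
#' @export
#' @examples
#' weighted_manhattan(c(0, 5), c(2, 100), c(1, 0))  # 2
weighted_manhattan <- function(p, q, w) {
  if (length(p) != length(q) || length(p) != length(w)) {
    abort("`p`, `q` and `w` must have the same length.",
          class = "lhda_error_dimension")
  }
  if (any(w < 0)) {
    abort("weights must be nonnegative.", class = "lhda_error_validation")
  }
  sum(w * abs(p - q))
}

# weighted L1 distances between rows of A and rows of B (C++ kernel)
.wl1_cross <- function(A, B, w) .wl1_cross_cpp(A, B, as.numeric(w))

# weighted L1 distances from point x to each row of A
.wl1_to_point <- function(A, x, w) .wl1_to_point_cpp(A, as.numeric(x), as.numeric(w))

.check_weights <- function(w, d) {
  if (length(w) != d) {
    abort(sprintf("weight vector has length %d, expected %d.", length(w), d),
          class = "lhda_error_dimension")
  }
  if (any(w < 0)) {
    abort("weights must be nonnegative.", class = "lhda_error_validation")
  }
  if (all(w == 0)) {
    abort("all-zero weight vector is invalid for distance computation.",
          class = "lhda_error_validation")
  }
  invisible(TRUE)
}
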