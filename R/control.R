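#' Tuning parameters for weight learning and classification
#'
#' @param k Neighbours per local hyperplane (default 3).
#' @param lambda Nonnegative l1 penalty on the feature weights. The margin
#'   term of the objective lives in `[0, 1]` and `||w||_1 = 1` at
#'   initialisation, so `lambda` is the fraction of that range the penalty
#'   occupies at the start; the default 0.01 applies gentle sparsity pressure
#'   without letting the penalty dominate the margin signal.
#' @param beta Sigmoid slope of the smoothed step function (default 5).
#' @param eta Initial gradient step size; backtracking halves it within each
#'   iteration, so the exact value is uncritical.
#' @param max_iter Maximum number of alternation iterations.
#' @param tol Convergence threshold on the l1 change of the normalised
#'   weight profile, `|| w_new/sum(w_new) - w/sum(w) ||_1`. Scale-free,
#'   because the l1 penalty keeps shrinking the overall scale of `w` while
#'   classification and margins depend only on the profile.
#' @param solver_mode `"exact"` (linear-program solve of the true weighted-L1
#'   hyperplane projection; default) or `"surrogate"` (linearised bound whose
#'   optimum collapses to the nearest single neighbour).
#' @param ratio_cap Finite stand-in for an infinite margin ratio when the
#'   nearest-miss distance is exactly zero.
#' @param max_halvings Backtracking halvings allowed per iteration.
#' @param keep_weight_path If `TRUE`, store the weight vector after every
#'   iteration in the training trace.
#' @return A list of class `lhda_control`.
#' @export
lhda_control <- function(k = 3, lambda = 0.01, beta = 5, eta = 0.1,
                         max_iter = 300, tol = 1e-4,
                         solver_mode = c("exact", "surrogate"),
                         ratio_cap = 1e6, max_halvings = 30,
                         keep_weight_path = FALSE) {
  solver_mode <- match.arg(solver_mode)
  stopifnot(k >= 1, lambda >= 0, beta > 0, eta > 0, max_iter >= 1,
            tol > 0, ratio_cap > 0, max_halvings >= 0)
  structure(list(k = as.integer(k), lambda = lambda, beta = beta, eta = eta,
                 max_iter = as.integer(max_iter), tol = tol,
                 solver_mode = solver_mode, ratio_cap = ratio_cap,
                 max_halvings = as.integer(max_halvings),
                 keep_weight_path = keep_weight_path),
            class = "lhda_control")
}
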