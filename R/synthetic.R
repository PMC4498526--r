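#' Fermat's-spiral benchmark data
#'
#' Two interleaved spiral arms (\eqn{r = \sqrt\theta}, the Fermat
#' parameterisation with unit scale) form the classes: class 1 points are
#' \eqn{(r\cos\theta, r\sin\theta)} with \eqn{\theta} drawn uniformly from
#' `theta_range`, class 2 is the point-reflected arm \eqn{(-x_1, -x_2)} from
#' an independent draw. Labels are completely determined by these first two
#' features; `noise_dim` additional irrelevant features are i.i.d. standard
#' normal. The benchmark stresses feature weighting: a good learner should
#' assign the noise features near-zero weight regardless of their number.
#'
#' @param n_per_class Samples per arm (default 200).
#' @param noise_dim Number of irrelevant standard-normal features.
#' @param theta_range Angle interval sampled (default `c(0.25, 4 * pi)`,
#'   about two turns per arm).
#' @param seed Optional integer; when given the output is reproducible and
#'   the caller's RNG state is untouched.
#' @param standardize If `TRUE`, centre and scale the two informative
#'   features to zero mean and unit variance so signal and noise share scale.
#'   Default `FALSE`: the raw spiral coordinates are kept, as in the classic
#'   setup where the noise is N(0, 1) against the unscaled arms.
#' @return A tibble with a `class` column (integer 1/2) followed by features
#'   `x1`, `x2`, `noise1..noise<noise_dim>`.
#' @export
#' @examples
#' d <- spiral_data(50, noise_dim = 3, seed = 1)
#' dim(d)
spiral_data <- function(n_per_class = 200, noise_dim = 0,
                        theta_range = c(0.25, 4 * pi), seed = NULL,
                        standardize = FALSE) {
  if (n_per_class < 1 || noise_dim < 0) {
    abort("`n_per_class` must be >= 1 and `noise_dim` >= 0.",
          class = "lhda_error_validation")
  }
  if (length(theta_range) != 2 || diff(theta_range) <= 0) {
    abort("`theta_range` must be an increasing interval.",
          class = "lhda_error_validation")
  }
  gen <- function() {
    th1 <- stats::runif(n_per_class, theta_range[1], theta_range[2])
    arm1 <- sqrt(th1) * cbind(cos(th1), sin(th1))
    th2 <- stats::runif(n_per_class, theta_range[1], theta_range[2])
    arm2 <- -sqrt(th2) * cbind(cos(th2), sin(th2))
    X <- rbind(arm1, arm2)
    if (standardize) X <- scale(X)
    noise <- if (noise_dim > 0) {
      matrix(stats::rnorm(2 * n_per_class * noise_dim), ncol = noise_dim)
    }
    list(X = X, noise = noise)
  }
  parts <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  out <- tibble::tibble(class = rep(1:2, each = n_per_class),
                        x1 = parts$X[, 1], x2 = parts$X[, 2])
  if (noise_dim > 0) {
    noise <- as.data.frame(parts$noise)
    names(noise) <- paste0("noise", seq_len(noise_dim))
    out <- dplyr::bind_cols(out, tibble::as_tibble(noise))
  }
  out
}

#' Gaussian-blob toy data
#'
#' Balanced Gaussian classes whose means differ only along the first
#' `informative_dims` features (spaced `separation` apart per class);
#' remaining `noise_dim` features are i.i.d. standard normal in every class.
#' A unit-variance fixture generator for testing weight recovery and
#' classification.
#'
#' @param n_per_class Samples per class.
#' @param n_classes Number of classes (default 2).
#' @param informative_dims Number of informative features (default 1).
#' @param noise_dim Number of pure-noise features (default 0).
#' @param separation Distance between consecutive class means along each
#'   informative feature; must be positive.
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @return A tibble with `class` (integer) and feature columns.
#' @export
blob_data <- function(n_per_class, n_classes = 2, informative_dims = 1,
                      noise_dim = 0, separation = 4, seed = NULL) {
  if (n_per_class < 1 || n_classes < 2 || informative_dims < 1 ||
      noise_dim < 0) {
    abort("counts must be positive (noise_dim may be zero).",
          class = "lhda_error_validation")
  }
  if (separation <= 0) {
    abort("`separation` must be positive.", class = "lhda_error_validation")
  }
  D <- informative_dims + noise_dim
  gen <- function() {
    X <- matrix(stats::rnorm(n_per_class * n_classes * D), ncol = D)
    for (cc in seq_len(n_classes)) {
      rows <- seq_len(n_per_class) + (cc - 1) * n_per_class
      X[rows, seq_len(informative_dims)] <-
        X[rows, seq_len(informative_dims)] + (cc - 1) * separation
    }
    X
  }
  X <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  colnames(X) <- c(paste0("inf", seq_len(informative_dims)),
                   if (noise_dim > 0) paste0("noise", seq_len(noise_dim)))
  dplyr::bind_cols(tibble::tibble(class = rep(seq_len(n_classes),
                                              each = n_per_class)),
                   tibble::as_tibble(as.data.frame(X)))
}
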