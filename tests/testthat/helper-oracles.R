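# Brute-force oracles and fixture builders shared across the suite.
# Everything here is deliberately simple, straight-line code, independent of
# the package's optimised paths.

# all alpha vectors on the k-simplex with coordinates on a grid of the given
# step (compositions), as a matrix with one alpha per row
simplex_grid <- function(k, step) {
  if (k == 1) return(matrix(1, 1, 1))
  m <- round(1 / step)
  parts <- expand.grid(rep(list(0:m), k - 1))
  keep <- rowSums(parts) <= m
  parts <- as.matrix(parts[keep, , drop = FALSE])
  cbind(parts, m - rowSums(parts)) / m
}

grid_objective <- function(A, x, H, w) {
  # rows of A are alpha vectors; returns w^T |x - H alpha| per row
  S <- A %*% t(H)                       # n_alpha x D
  abs(sweep(S, 2, x)) %*% w
}

# exhaustive grid search for min_alpha w^T |x - H alpha| over the simplex:
# coarse pass at `step`, then exhaustive passes at step/10 in the boxes
# around the best coarse points (several, because near-optimal basins can be
# far apart); still pure enumeration
grid_alpha_min <- function(x, H, w, step = 0.01, n_refine = 20) {
  k <- ncol(H)
  A <- simplex_grid(k, step)
  v <- grid_objective(A, x, H, w)
  out <- min(v)
  for (idx in order(v)[seq_len(min(n_refine, length(v)))]) {
    best <- A[idx, ]
    lo <- pmax(best - step, 0)
    fine <- lapply(seq_len(k - 1), function(i) {
      seq(lo[i], min(best[i] + step, 1), by = step / 10)
    })
    Af <- as.matrix(expand.grid(fine))
    s <- rowSums(Af)
    Af <- cbind(Af, 1 - s)[s <= 1 + 1e-12, , drop = FALSE]
    Af[Af[, k] < 0, k] <- 0
    out <- min(out, grid_objective(Af, x, H, w))
  }
  out
}

# plain weighted 1-nearest-neighbour prediction (ties: lowest sample index)
nn1_predict <- function(Xtr, ytr, Xte, w) {
  apply(Xte, 1, function(x) {
    d <- colSums(w * abs(t(Xtr) - x))
    ytr[which.min(d)]
  })
}

# unweighted 1-NN leave-one-out accuracy
nn1_loocv <- function(X, y) {
  n <- nrow(X)
  pred <- vapply(seq_len(n), function(i) {
    d <- colSums(abs(t(X[-i, , drop = FALSE]) - X[i, ]))
    y[-i][which.min(d)]
  }, y[1])
  mean(pred == y)
}

# well-separated two-class blob fixture used throughout
sep_blobs <- function(n_per_class = 10, noise_dim = 2, seed = 42,
                      separation = 12) {
  blob_data(n_per_class, n_classes = 2, informative_dims = 1,
            noise_dim = noise_dim, separation = separation, seed = seed)
}

# random small dataset for oracle comparisons
random_dataset <- function(n_per_class, d, seed) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(2 * n_per_class * d), ncol = d)
    colnames(X) <- paste0("f", seq_len(d))
    dplyr::bind_cols(tibble::tibble(class = rep(1:2, each = n_per_class)),
                     tibble::as_tibble(as.data.frame(X)))
  })
}
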