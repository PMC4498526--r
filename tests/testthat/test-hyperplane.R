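test_that("weighted Manhattan distance evaluates the defining formula", {
  expect_equal(weighted_manhattan(c(3, -1, 2), c(3, -1, 2), runif(3)), 0)
  expect_equal(weighted_manhattan(c(0, 5), c(2, 100), c(1, 0)), 2)
  expect_equal(weighted_manhattan(c(0, 0), c(1, 3), c(0.5, 0.5)), 2.0)
  # symmetry on random inputs
  withr::with_seed(1, {
    for (i in 1:5) {
      p <- rnorm(4); q <- rnorm(4); w <- runif(4)
      expect_equal(weighted_manhattan(p, q, w), weighted_manhattan(q, p, w))
    }
  })
  expect_error(weighted_manhattan(1:3, 1:2, c(1, 1)),
               class = "lhda_error_dimension")
  expect_error(weighted_manhattan(1:2, 1:2, c(1, -1)),
               class = "lhda_error_validation")
})

test_that("class neighbour search respects class, exclusion and index tie-breaks", {
  d <- random_dataset(6, 3, seed = 7)
  ds <- as_lhda_dataset(d)
  w <- rep(1, 3)
  # k = class size returns the whole class
  expect_setequal(class_neighbors(rnorm(3), ds, 1, 6, w), which(ds$y == 1))
  # self-exclusion drops the query row
  nb <- class_neighbors(ds$x[2, ], ds, 1, 5, w, exclude_index = 2)
  expect_false(2 %in% nb)
  # equidistant candidates resolved by ascending sample index:
  # three samples of class 1 at the same distance from the query
  eq <- tibble::tibble(class = c(1, 1, 1, 2, 2),
                       x1 = c(1, -1, 1, 5, 6), x2 = c(0, 0, 0, 5, 6))
  got <- class_neighbors(c(0, 0), eq, 1, 2, c(1, 1))
  # brute-force check: all three candidates tie at distance 1
  dists <- apply(as.matrix(eq[1:3, -1]), 1, weighted_manhattan,
                 q = c(0, 0), w = c(1, 1))
  expect_true(all(dists == dists[1]))
  expect_identical(got, c(1L, 2L))
  expect_error(class_neighbors(c(0, 0), eq, 2, 3, c(1, 1)),
               class = "lhda_error_insufficient_neighbors")
})

test_that("spanning coefficients: degenerate cases in both solver modes", {
  for (mode in c("exact", "surrogate")) {
    expect_equal(spanning_coefficients(c(1, 2), cbind(c(0, 0)), c(1, 1),
                                       mode = mode), 1)
    # query equal to one neighbour: that vertex, distance zero
    H <- cbind(c(0, 0, 1), c(2, -1, 3), c(1, 1, 1))
    al <- spanning_coefficients(c(2, -1, 3), H, c(0.2, 0.5, 0.3), mode = mode)
    expect_equal(al, c(0, 1, 0), tolerance = 1e-9)
  }
  # surrogate tie: two coincident nearest neighbours split uniformly
  H <- cbind(c(0, 0), c(0, 0), c(5, 5))
  al <- spanning_coefficients(c(0.1, 0), H, c(1, 1), mode = "surrogate")
  expect_equal(al, c(0.5, 0.5, 0))
})

test_that("exact solve matches the simplex-grid oracle and beats the linearised bound", {
  withr::with_seed(11, {
    for (rep in 1:40) {
      D <- sample(2:6, 1)
      k <- sample(2:4, 1)
      H <- matrix(rnorm(D * k), D, k)
      x <- rnorm(D)
      w <- runif(D)
      w <- w / sum(w)
      al <- spanning_coefficients(x, H, w, mode = "exact")
      f_exact <- sum(w * abs(x - drop(H %*% al)))
      f_grid <- grid_alpha_min(x, H, w)
      expect_lt(abs(f_exact - f_grid), 1e-3)
      # never worse than any single neighbour (z_i bound), nor the surrogate
      z <- apply(H, 2, function(h) sum(w * abs(x - h)))
      expect_lte(f_exact, min(z) + 1e-9)
      als <- spanning_coefficients(x, H, w, mode = "surrogate")
      f_sur <- sum(w * abs(x - drop(H %*% als)))
      expect_lte(f_exact, f_sur + 1e-9)
    }
  })
})

test_that("local hyperplane distance: hull membership, k = 1, and oracle agreement", {
  # x constructed inside the hull of its class neighbours -> distance 0
  base <- tibble::tibble(class = c(1, 1, 1, 2, 2, 2),
                         x1 = c(0, 4, 0, 9, 10, 11),
                         x2 = c(0, 0, 4, 9, 10, 11),
                         x3 = c(1, 1, 1, 8, 9, 10))
  x_in <- 0.3 * c(0, 0, 1) + 0.3 * c(4, 0, 1) + 0.4 * c(0, 4, 1)
  lh <- local_hyperplane(x_in, base, 1, k = 3, w = c(1, 1, 1))
  expect_lt(lh$distance, 1e-9)
  expect_equal(lh$projection, drop(lh$neighbor_matrix %*% lh$alpha))
  expect_true(all(lh$neighbor_indices %in% 1:3))
  # k = 1 reduces to the nearest single neighbour
  lh1 <- local_hyperplane(c(0.5, 0, 0), base, 1, k = 1, w = c(1, 1, 1))
  expect_equal(lh1$distance,
               weighted_manhattan(c(0.5, 0, 0), c(0, 0, 1), c(1, 1, 1)))
  # random instances against the grid oracle
  withr::with_seed(3, {
    for (rep in 1:10) {
      d <- random_dataset(5, 4, seed = rep + 100)
      ds <- as_lhda_dataset(d)
      w <- runif(4); w <- w / sum(w)
      x <- rnorm(4)
      lh <- local_hyperplane(x, ds, 1, k = 3, w = w)
      H <- lh$neighbor_matrix
      expect_lt(abs(lh$distance - grid_alpha_min(x, H, w)), 1e-3)
    }
  })
})

test_that("distances scale linearly in w and decisions are scale-invariant", {
  d <- random_dataset(6, 4, seed = 19)
  ds <- as_lhda_dataset(d)
  w <- runif(4)
  x <- rnorm(4)
  for (mode in c("exact", "surrogate")) {
    lh1 <- local_hyperplane(x, ds, 1, k = 3, w = w, mode = mode)
    lh2 <- local_hyperplane(x, ds, 1, k = 3, w = 7 * w, mode = mode)
    expect_equal(lh2$distance, 7 * lh1$distance, tolerance = 1e-9)
    expect_identical(lh1$neighbor_indices, lh2$neighbor_indices)
  }
})
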