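test_that("smoothed step function identities hold for a range of slopes", {
  for (beta in c(0.5, 1, 5, 20)) {
    expect_equal(sigmoid_step(1, beta), 0.5)
    expect_equal(sigmoid_step_deriv(1, beta), beta / 4)
    # monotone increasing (away from saturation)
    z <- seq(-1, 2, length.out = 30)
    expect_true(all(diff(sigmoid_step(z, beta)) > 0))
  }
  expect_equal(sigmoid_step(1 + log(3), 1), 0.75)
  # numerically stable far out in both tails
  expect_equal(sigmoid_step(1e7, 5), 1)
  expect_equal(sigmoid_step(-1e7, 5), 0)
  expect_equal(sigmoid_step_deriv(1e7, 5), 0)
})

test_that("margin ratio covers the regular and degenerate regimes", {
  ctrl <- lhda_control(k = 1)
  # symmetric configuration: hit and miss equally far -> ratio 1
  sym <- tibble::tibble(class = c(1, 1, 2, 2),
                        x1 = c(0, 2, -2, -8), x2 = c(0, 0, 0, 0))
  mr <- margin_ratio(1, sym, w = c(1, 1), control = ctrl)
  expect_equal(mr$NH$distance, mr$NM$distance)
  expect_equal(mr$ratio, 1)
  # duplicate within the own class -> zero numerator -> ratio 0
  dup_hit <- tibble::tibble(class = c(1, 1, 2, 2),
                            x1 = c(0, 0, 5, 6), x2 = c(1, 1, 5, 6))
  expect_equal(margin_ratio(1, dup_hit, w = c(1, 1), control = ctrl)$ratio, 0)
  # duplicate in the other class, distinct within own -> capped ratio
  dup_miss <- tibble::tibble(class = c(1, 1, 2, 2),
                             x1 = c(0, 3, 0, 6), x2 = c(1, 3, 1, 6))
  expect_equal(margin_ratio(1, dup_miss, w = c(1, 1), control = ctrl)$ratio,
               ctrl$ratio_cap)
})

test_that("penalised objective: bounds, additive penalty, duplicate-implementation oracle", {
  ctrl <- lhda_control(k = 2, beta = 20, lambda = 0)
  # perfectly separated classes, large slope: margin term vanishes
  d <- sep_blobs(n_per_class = 8, noise_dim = 1, separation = 50)
  D <- 2
  v <- rep(1 / sqrt(D), D)
  expect_lt(penalized_objective(d, v, ctrl), 1e-6)
  # penalty is exactly additive in lambda
  d2 <- random_dataset(5, 3, seed = 5)
  v2 <- runif(3) + 0.1
  ctrl0 <- lhda_control(k = 2, lambda = 0)
  ctrl1 <- lhda_control(k = 2, lambda = 1)
  expect_equal(penalized_objective(d2, v2, ctrl1) -
                 penalized_objective(d2, v2, ctrl0),
               sum(v2^2))
  # straight-line re-evaluation from exported primitives only
  ctrl3 <- lhda_control(k = 2, lambda = 0.3, beta = 4)
  d3 <- random_dataset(4, 3, seed = 9)
  ds3 <- as_lhda_dataset(d3)
  v3 <- withr::with_seed(2, runif(3) + 0.2)
  w3 <- v3^2
  ratios <- vapply(seq_len(ds3$n), function(i) {
    dNH <- local_hyperplane(ds3$x[i, ], ds3,
                            ds3$class_labels[ds3$y[i]], ctrl3$k, w3,
                            exclude_index = i)$distance
    other <- setdiff(ds3$class_labels, ds3$class_labels[ds3$y[i]])
    dNM <- min(vapply(other, function(cl) {
      local_hyperplane(ds3$x[i, ], ds3, cl, ctrl3$k, w3)$distance
    }, numeric(1)))
    if (dNM == 0) (if (dNH == 0) 1 else ctrl3$ratio_cap) else dNH / dNM
  }, numeric(1))
  straight <- mean(1 / (1 + exp(ctrl3$beta * (1 - ratios)))) +
    ctrl3$lambda * sum(w3)
  expect_equal(penalized_objective(d3, v3, ctrl3), straight,
               tolerance = 1e-12)
})

test_that("analytic gradient: structural zeros, duplicated-feature symmetry", {
  ctrl <- lhda_control(k = 2)
  d <- random_dataset(5, 3, seed = 13)
  terms <- margin_terms(d, rep(1 / 3, 3), ctrl)
  g0 <- objective_gradient(d, rep(0, 3), ctrl, terms = terms)
  expect_identical(g0, rep(0, 3))
  # duplicated feature with equal v -> equal gradient components
  d2 <- random_dataset(5, 2, seed = 17)
  d2$f3 <- d2$f1
  v <- c(0.6, 0.4, 0.6)
  g <- objective_gradient(d2, v, ctrl)
  expect_equal(g[1], g[3], tolerance = 1e-12)
})

test_that("frozen-hyperplane gradient agrees with central finite differences", {
  ctrl <- lhda_control(k = 2, lambda = 0.05, beta = 4)
  withr::with_seed(23, {
    for (rep in 1:6) {
      d <- random_dataset(5, 4, seed = 300 + rep)
      ds <- as_lhda_dataset(d)
      v <- runif(4) + 0.3
      mp <- lhda:::.margin_pass(ds, v^2, ctrl)
      terms <- margin_terms(ds, v^2, ctrl)
      g <- objective_gradient(ds, v, ctrl, terms = terms)
      h <- 1e-6
      for (j in 1:4) {
        vp <- v; vp[j] <- vp[j] + h
        vm <- v; vm[j] <- vm[j] - h
        fd <- (lhda:::.frozen_objective(vp, mp, ctrl) -
                 lhda:::.frozen_objective(vm, mp, ctrl)) / (2 * h)
        expect_lt(abs(g[j] - fd) / max(abs(fd), 1e-8), 1e-5)
      }
    }
  })
})

test_that("weight learning recovers the informative feature on blobs", {
  d <- blob_data(12, 2, informative_dims = 1, noise_dim = 4,
                 separation = 8, seed = 31)
  fit <- lhda_fit(d, control = lhda_control(k = 2, max_iter = 60))
  w <- unname(fit$w)
  expect_identical(which.max(w), 1L)
  # cross-check: feature 1 is also the best single feature by 1-NN accuracy
  ds <- as_lhda_dataset(d)
  acc1 <- vapply(seq_len(ds$d), function(j) {
    nn1_loocv(ds$x[, j, drop = FALSE], ds$y)
  }, numeric(1))
  expect_identical(which.max(acc1), 1L)
  # line-search contract: accepted frozen value never above the previous
  # objective
  tr <- fit$trace
  prev <- c(NA, head(tr$objective, -1))
  expect_true(all(tr$objective_frozen[-1] <= prev[-1] + 1e-9))
})

test_that("sparsity increases along a lambda grid", {
  d <- blob_data(10, 2, informative_dims = 1, noise_dim = 5,
                 separation = 8, seed = 37)
  l1 <- vapply(c(0.001, 0.05, 0.5), function(lam) {
    f <- lhda_fit(d, control = lhda_control(k = 2, lambda = lam,
                                            max_iter = 40))
    sum(f$w)
  }, numeric(1))
  expect_true(all(diff(l1) < 0))
})

test_that("weight learning validates class sizes up front", {
  d <- tibble::tibble(class = c(1, 1, 2, 2), x1 = rnorm(4), x2 = rnorm(4))
  expect_error(lhda_fit(d, control = lhda_control(k = 2)),
               class = "lhda_error_insufficient_neighbors")
})
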