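test_that("k-best selection ranks by absolute correlation with stated tie-breaks", {
  set.seed(20)
  n <- 40
  X <- matrix(rnorm(n * 10), n, 10)
  y <- rnorm(n)
  X[, 7] <- y + rnorm(n, 0, 0.01)
  expect_equal(kbest_select(X, y, 1), 7L)
  expect_equal(kbest_select(X, y, ncol(X)), 1:10)

  # exact duplicate features tie; the lower index wins
  X2 <- cbind(X[, 7], X[, 7], X[, 1:3])
  expect_equal(kbest_select(X2, y, 1), 1L)

  # a constant feature scores 0 and loses to any informative feature
  X3 <- cbind(rep(1, n), y + rnorm(n, 0, 0.5))
  expect_equal(kbest_select(X3, y, 1), 2L)
  expect_error(kbest_select(X, rep(1, n), 2), "constant")
})

test_that("ridge matches the closed-form normal equations", {
  # forced example: X = I2 treated as pre-centered
  f <- fit_ridge(diag(2), c(1, 2), alpha = 1, center = FALSE)
  expect_equal(f$weights, c(0.5, 1.0))

  set.seed(21)
  for (rep in 1:5) {
    X <- matrix(rnorm(30), 10, 3)
    y <- rnorm(10)
    alpha <- runif(1, 0.01, 5)
    f <- fit_ridge(X, y, alpha)
    xc <- scale(X, scale = FALSE)
    w_oracle <- solve(crossprod(xc) + diag(alpha, 3),
                      crossprod(xc, y - mean(y)))
    expect_equal(f$weights, as.numeric(w_oracle), tolerance = 1e-8)
  }
})

test_that("ridge limiting cases: OLS at alpha 0, null model at huge alpha", {
  set.seed(22)
  X <- matrix(rnorm(60), 20, 3)
  y <- rnorm(20)
  f0 <- fit_ridge(X, y, 0)
  ls <- lm(y ~ X)
  expect_equal(f0$weights, unname(coef(ls)[-1]), tolerance = 1e-10)
  expect_equal(f0$intercept, unname(coef(ls)[1]), tolerance = 1e-10)
  fbig <- fit_ridge(X, y, 1e9)
  expect_lt(max(abs(fbig$weights)), 1e-6)
  expect_equal(fbig$intercept, mean(y), tolerance = 1e-4)
  expect_error(fit_ridge(X, y, -1), "non-negative")
})

test_that("nested LOPO engine agrees with the plain-R reference", {
  set.seed(23)
  for (rep in 1:3) {
    n <- 14
    X <- matrix(rnorm(n * 9), n, 9)
    y <- rnorm(n) + X[, 3]
    fit <- nested_cv_discover(X, y, grid = list(k = c(2, 4), alpha = c(0.01, 1)))
    ref <- ref_outer_lopo(X, y, c(2, 4), c(0.01, 1))
    expect_equal(fit$report$outer_pred, ref, tolerance = 1e-10)
    hp <- ref_inner_select(X, y, c(2, 4), c(0.01, 1))
    expect_equal(fit$model$k, hp$k)
    expect_equal(fit$model$alpha, hp$alpha)
  }
})

test_that("held-out subjects cannot leak into their fold's model", {
  set.seed(24)
  n <- 15
  X <- matrix(rnorm(n * 12), n, 12)
  y <- X[, 2] + rnorm(n, 0, 0.5)
  grid <- list(k = c(2, 4), alpha = c(0.1, 1))
  base <- nested_cv_discover(X, y, grid = grid)
  i <- 6
  X2 <- X
  X2[i, ] <- sample(X[i, ]) * 3 + 1 # corrupt the held-out subject's features
  mod <- nested_cv_discover(X2, y, grid = grid)
  expect_identical(base$report$fold_models[[i]]$selected,
                   mod$report$fold_models[[i]]$selected)
  expect_equal(base$report$fold_models[[i]]$weights,
               mod$report$fold_models[[i]]$weights, tolerance = 1e-12)
  # the held-out prediction itself must of course change
  expect_false(isTRUE(all.equal(base$report$outer_pred[i],
                                mod$report$outer_pred[i])))
})

test_that("with all features and alpha 0 the folds reduce to OLS LOPO", {
  set.seed(25)
  n <- 12
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rnorm(n) + X[, 1]
  fit <- nested_cv_discover(X, y, grid = list(k = 3, alpha = 0))
  ols <- vapply(seq_len(n), function(o) {
    f <- lm(y[-o] ~ X[-o, , drop = FALSE])
    unname(coef(f)[1] + sum(coef(f)[-1] * X[o, ]))
  }, numeric(1))
  expect_equal(fit$report$outer_pred, ols, tolerance = 1e-8)
})

test_that("degenerate discovery inputs are refused", {
  set.seed(26)
  X <- matrix(rnorm(200), 20, 10)
  expect_error(nested_cv_discover(X, rep(3, 20)), "constant")
  expect_error(nested_cv_discover(X[1:5, ], rnorm(5)), "at least 10")
})

test_that("a pure-noise target yields near-zero median internal correlation", {
  set.seed(27)
  rs <- replicate(20, {
    X <- matrix(rnorm(20 * 40), 20, 40)
    y <- rnorm(20)
    nested_cv_discover(X, y, grid = list(k = c(5, 10), alpha = c(0.1, 1)))$report$r_internal
  })
  expect_lt(abs(median(rs)), 0.15)
})

test_that("internal performance grows with planted effect size", {
  median_r <- vapply(c(0.05, 0.7), function(es) {
    rs <- vapply(1:5, function(s) {
      spec <- cohort_spec(n_subjects = 25, n_nodes = 8, n_timepoints = 150,
                          true_edges = 2, effect_size = es, seed = 400 + s,
                          label = "c")
      coh <- generate_cohort(spec)
      X <- cohort_edge_matrix(coh)
      nested_cv_discover(X, coh$ground_truth$y,
                         grid = list(k = c(2, 5), alpha = c(0.1, 1)))$report$r_internal
    }, numeric(1))
    median(rs)
  }, numeric(1))
  expect_gt(median_r[2], median_r[1])
})

test_that("permutation p-values follow the exceedance formula and its floor", {
  set.seed(28)
  n <- 20
  X <- matrix(rnorm(n * 15), n, 15)
  y <- X[, 5] * 3 + rnorm(n, 0, 0.3) # strong planted signal
  pt <- permutation_test(X, y, grid = list(k = c(2, 4), alpha = c(0.1, 1)),
                         B = 99, seed = 29)
  expect_equal(pt$p, 0.01) # observed beats all 99 null draws: formula floor
  expect_equal(pt$p, (1 + sum(pt$null_r >= pt$observed_r)) / (pt$B + 1))
  pt2 <- permutation_test(X, y, grid = list(k = c(2, 4), alpha = c(0.1, 1)),
                          B = 99, seed = 29)
  expect_identical(pt$null_r, pt2$null_r)
  expect_error(permutation_test(X, y, B = 50), ">= 99")
})

test_that("frozen models survive a serialize/load round trip bit-exactly", {
  set.seed(30)
  n <- 15
  X <- matrix(rnorm(n * 12), n, 12)
  y <- X[, 4] + rnorm(n, 0, 0.5)
  fit <- nested_cv_discover(X, y, grid = list(k = c(2, 4), alpha = c(0.001, 1)))
  path <- tempfile(fileext = ".json")
  freeze_model(fit$model, path)
  reloaded <- load_model(path)
  newx <- matrix(rnorm(5 * 12), 5, 12)
  expect_identical(predict(fit$model, newx), predict(reloaded, newx))
  expect_identical(reloaded$selected_edges, fit$model$selected_edges)
  expect_identical(reloaded$alpha, fit$model$alpha)
})

test_that("published-style hyperparameters serialize verbatim", {
  m <- new_frozen_model(selected_edges = 0:9, weights = rnorm(10),
                        intercept = 25, k = 10, alpha = 0.001,
                        center = rnorm(10), scale = rep(1, 10),
                        n_nodes = 123)
  path <- tempfile(fileext = ".json")
  freeze_model(m, path)
  reloaded <- load_model(path)
  expect_identical(reloaded$k, 10L)
  expect_identical(reloaded$alpha, 0.001)
  raw <- jsonlite::read_json(path)
  expect_equal(raw$alpha, 0.001)
  expect_equal(raw$k, 10L)
})

test_that("tampered or mismatched model files are refused", {
  m <- new_frozen_model(selected_edges = c(0L, 3L), weights = c(1, -1),
                        intercept = 0, k = 2, alpha = 0.1,
                        center = c(0, 0), scale = c(1, 1), n_nodes = 5)
  path <- tempfile(fileext = ".json")
  freeze_model(m, path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$selected_edges <- raw$selected_edges[1] # drop an edge
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(path), "k = 2")

  freeze_model(m, path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$ordering_version <- "something-else/v9"
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(path), "ordering")
})
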