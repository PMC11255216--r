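test_that("timeseries standardization is a per-column z-score and idempotent", {
  set.seed(10)
  ts <- matrix(rnorm(600, mean = 3, sd = 4), 100, 6,
               dimnames = list(NULL, sprintf("n%d", 1:6)))
  z <- standardize_timeseries(ts)
  expect_lt(max(abs(colMeans(z))), 1e-8)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 6), tolerance = 1e-8)
  expect_equal(unname(standardize_timeseries(z)), unname(z), tolerance = 1e-8)
  expect_equal(as.numeric(standardize_timeseries(cbind(x = c(1, 2, 3)))),
               c(-1, 0, 1))
  ts[, 2] <- 7
  expect_error(standardize_timeseries(ts), "n2")
})

test_that("independent signals give near-zero partial correlations", {
  set.seed(11)
  tt <- 4000
  ts <- matrix(rnorm(tt * 6), tt, 6)
  pc <- partial_correlation(ts, shrinkage = "none")
  off <- abs(pc[upper.tri(pc)])
  expect_gt(mean(off < 3 / sqrt(tt)), 0.99 - 1e-9)
})

test_that("a chain graph has zero 1-3 partial correlation but strong marginal", {
  set.seed(12)
  tt <- 10000
  x1 <- rnorm(tt)
  x2 <- x1 + rnorm(tt)
  x3 <- x2 + rnorm(tt)
  ts <- cbind(x1, x2, x3)
  pc <- partial_correlation(ts, shrinkage = "none")
  expect_lt(abs(pc[1, 3]), 0.05)
  expect_gt(cor(x1, x3), 0.3)
  oracle <- pcor_residual_oracle(ts)
  expect_equal(pc[1, 3], oracle[1, 3], tolerance = 1e-3)
})

test_that("exact partial correlation matches the residual-regression oracle", {
  set.seed(13)
  for (m in c(4, 5)) {
    tt <- 2000
    mix <- matrix(rnorm(m * m, 0, 0.4), m, m) + diag(m)
    ts <- matrix(rnorm(tt * m), tt, m) %*% mix
    pc <- partial_correlation(ts, shrinkage = "none")
    oracle <- pcor_residual_oracle(ts)
    expect_lt(max(abs(pc - oracle)), 1e-6)
  }
})

test_that("estimates converge to the closed form -P_ij/sqrt(P_ii P_jj)", {
  set.seed(14)
  m <- 4
  omega <- diag(m)
  omega[1, 2] <- omega[2, 1] <- 0.4
  omega[2, 3] <- omega[3, 2] <- -0.3
  omega[3, 4] <- omega[4, 3] <- 0.2
  truth <- -omega / sqrt(tcrossprod(diag(omega)))
  diag(truth) <- 1
  sigma <- solve(omega)
  ts <- matrix(rnorm(50000 * m), ncol = m) %*% chol(sigma)
  pc <- partial_correlation(ts, shrinkage = "none")
  expect_lt(max(abs(pc - truth)), 0.02)
})

test_that("analytic shrinkage beats no shrinkage when T < 2M", {
  set.seed(15)
  m <- 30
  tt <- 40
  omega <- diag(m)
  idx <- cbind(sample(m, 10), sample(m, 10))
  idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
  for (r in seq_len(nrow(idx))) {
    v <- runif(1, -0.2, 0.2)
    omega[idx[r, 1], idx[r, 2]] <- omega[idx[r, 2], idx[r, 1]] <- v
  }
  omega <- omega + diag(max(0, 0.1 - min(eigen(omega)$values)), m)
  truth <- -omega / sqrt(tcrossprod(diag(omega)))
  diag(truth) <- 1
  sigma <- solve(omega)
  ch <- chol(sigma)
  gain <- replicate(20, {
    ts <- matrix(rnorm(tt * m), tt, m) %*% ch
    d_auto <- norm(partial_correlation(ts, "auto") - truth, "F")
    d_none <- norm(partial_correlation(ts, "none") - truth, "F")
    d_none - d_auto
  })
  expect_gt(median(gain), 0)
})

test_that("singular covariance without shrinkage is refused with advice", {
  set.seed(16)
  ts <- matrix(rnorm(5 * 10), 5, 10) # T < M: singular
  expect_error(partial_correlation(ts, shrinkage = "none"), "shrinkage")
  expect_silent(partial_correlation(ts, shrinkage = "auto"))
})

test_that("edge vectorization follows the row-major upper-triangle order", {
  cm <- matrix(0, 3, 3)
  cm[1, 2] <- cm[2, 1] <- 0.1
  cm[1, 3] <- cm[3, 1] <- 0.2
  cm[2, 3] <- cm[3, 2] <- 0.3
  diag(cm) <- 1
  v <- vectorize_connectivity(cm)
  expect_equal(as.numeric(v), c(0.1, 0.2, 0.3))
  expect_equal(attr(v, "ordering_version"), EDGE_ORDERING_VERSION)

  # 123 nodes (122 regions + global signal) --> 7503 edges
  expect_equal(n_edges(123), 7503L)
  set.seed(17)
  big <- matrix(rnorm(123^2), 123)
  big <- (big + t(big)) / 2
  diag(big) <- 1
  vb <- vectorize_connectivity(big)
  expect_length(vb, 7503L)
  expect_equal(devectorize_connectivity(vb), big)

  asym <- cm
  asym[1, 2] <- 0.4
  expect_error(vectorize_connectivity(asym), "symmetric")
})

test_that("edge index <-> node pair mapping matches brute-force enumeration", {
  expect_equal(unname(edge_to_nodes(0, 123)[1, ]), c(0L, 1L))
  expect_equal(unname(edge_to_nodes(7502, 123)[1, ]), c(121L, 122L))
  m <- 10
  enum <- do.call(rbind, lapply(0:(m - 2), function(i) {
    cbind(i, (i + 1):(m - 1))
  }))
  got <- edge_to_nodes(0:(n_edges(m) - 1), m)
  expect_equal(unname(got), unname(enum))
  expect_equal(nodes_to_edge(enum[, 1], enum[, 2], m), 0:(n_edges(m) - 1))
  expect_error(edge_to_nodes(n_edges(m), m), "out of range")
})

test_that("the edge-matrix pipeline carries labels and attributes", {
  set.seed(18)
  ts_list <- lapply(1:3, function(i) {
    matrix(rnorm(100 * 5), 100, 5,
           dimnames = list(NULL, c(sprintf("r%d", 1:4), "global_signal")))
  })
  names(ts_list) <- sprintf("sub%d", 1:3)
  x <- edge_matrix(ts_list)
  expect_equal(dim(x), c(3L, 10L))
  expect_equal(rownames(x), names(ts_list))
  expect_equal(attr(x, "n_nodes"), 5L)
})

test_that("the packaged atlas fixture loads with the expected regions", {
  at <- load_atlas()
  expect_equal(nrow(at), 20L)
  expect_true(all(c("Amy", "pIns", "pCing") %in% at$label))
  expect_false(anyDuplicated(at$index) > 0)
})
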