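test_that("identical specs and seeds give bit-identical cohorts", {
  spec <- cohort_spec(n_subjects = 8, n_nodes = 8, n_timepoints = 60,
                      true_edges = 2, effect_size = 0.4, seed = 70,
                      label = "det")
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$ground_truth$y, b$ground_truth$y)
  expect_identical(a$timeseries[[3]], b$timeseries[[3]])
  expect_identical(a$behavior, b$behavior)
  expect_identical(a$covariates, b$covariates)
})

test_that("subject covariances stay positive definite even at high coupling", {
  spec <- cohort_spec(n_subjects = 12, n_nodes = 10, n_timepoints = 50,
                      true_edges = 4, coupling_sd = 1.0, effect_size = 0.5,
                      seed = 71, label = "pd")
  coh <- generate_cohort(spec)
  for (ts in coh$timeseries) {
    expect_true(all(is.finite(ts)))
    expect_silent(chol(cov(ts) + diag(1e-8, ncol(ts))))
  }
})

test_that("ground truth reconstructs the target exactly", {
  spec <- cohort_spec(n_subjects = 20, n_nodes = 8, n_timepoints = 60,
                      true_edges = 3, effect_size = 0.5, seed = 72,
                      label = "gt")
  coh <- generate_cohort(spec)
  gt <- coh$ground_truth
  y_rebuilt <- gt$intercept +
    gt$signal_scale * as.numeric(gt$latent %*% gt$weights) + gt$noise
  expect_equal(gt$y, y_rebuilt, tolerance = 1e-12)
})

test_that("the edge-driven variance share converges to the requested effect size", {
  spec <- cohort_spec(n_subjects = 500, n_nodes = 8, n_timepoints = 30,
                      true_edges = 2, effect_size = 0.3, seed = 73,
                      label = "share")
  # timeseries are irrelevant here; use the exported generative components
  coh <- generate_cohort(spec)
  gt <- coh$ground_truth
  signal <- gt$signal_scale * as.numeric(gt$latent %*% gt$weights)
  share <- var(signal) / var(gt$y)
  expect_lt(abs(share - 0.3), 0.1)
})

test_that("null cohorts leave edges uncorrelated with the target", {
  spec <- cohort_spec(n_subjects = 100, n_nodes = 8, n_timepoints = 120,
                      true_edges = 2, effect_size = 0, seed = 74,
                      label = "null")
  coh <- generate_cohort(spec)
  X <- cohort_edge_matrix(coh)
  r <- abs(as.numeric(cor(X, coh$ground_truth$y)))
  expect_gt(mean(r < 2 / sqrt(100)), 0.9)
})

test_that("strong coupling makes estimated edges track their latent strengths", {
  spec <- cohort_spec(n_subjects = 100, n_nodes = 8, n_timepoints = 260,
                      true_edges = 2, coupling_sd = 0.5, effect_size = 0.5,
                      seed = 75, label = "strong")
  coh <- generate_cohort(spec)
  X <- cohort_edge_matrix(coh)
  gt <- coh$ground_truth
  for (q in seq_along(gt$true_edge_indices)) {
    r <- abs(cor(X[, gt$true_edge_indices[q] + 1L], gt$latent[, q]))
    expect_gt(r, 0.5)
  }
})

test_that("ratings embed and recover the scores through the behaviour path", {
  set.seed(76)
  d <- rnorm(25, 25, 10)
  ratings <- generate_ratings_from_dvc(d, seed = 77)
  expect_true(all(ratings$value >= 0 & ratings$value <= 100))
  rec <- compute_dvc(ratings, "pain")
  expect_equal(rec$value, d, tolerance = 1e-9)

  flat <- generate_ratings_from_dvc(0, seed = 78)
  expect_equal(compute_dvc(flat, "pain")$value, 0, tolerance = 1e-12)
  dplus <- flat$value[flat$condition == "CS_plus_pain"]
  dminus <- flat$value[flat$condition == "CS_minus"]
  expect_equal(diff(dplus), diff(dminus), tolerance = 1e-12)

  expect_error(generate_ratings_from_dvc(250, seed = 79), "embedded")
})

test_that("the alternate-anchor cohort round-trips through harmonization", {
  spec <- cohort_spec(n_subjects = 15, n_nodes = 8, n_timepoints = 60,
                      true_edges = 2, effect_size = 0.4, seed = 80,
                      label = "vs2", scale_scheme = "vs2")
  coh <- generate_cohort(spec)
  expect_true(all(coh$behavior$value >= 0 & coh$behavior$value <= 100))
  scored <- score_cohort_behavior(coh)
  expect_equal(scored$value, coh$ground_truth$y, tolerance = 1e-9)
  # skipping harmonization would halve the recovered scores
  raw <- compute_dvc(coh$behavior, "pain")
  expect_equal(raw$value, 2 * coh$ground_truth$y, tolerance = 1e-9)
})

test_that("the study replica has the registered cohort structure", {
  rep <- make_study_replica(seed = 81, n_nodes = 12)
  expect_equal(length(rep$discovery$timeseries), 25L)
  expect_equal(length(rep$validation1$timeseries), 26L)
  expect_equal(length(rep$validation2$timeseries), 23L)
  expect_equal(nrow(rep$discovery$timeseries[[1]]), 260L)
  expect_equal(nrow(rep$validation2$timeseries[[1]]), 192L)
  expect_identical(rep$validation2$scale_scheme, "vs2")
  expect_identical(rep$discovery$scale_scheme, "default")
  # all cohorts share one generative template
  expect_identical(rep$discovery$ground_truth$true_edge_indices,
                   rep$validation2$ground_truth$true_edge_indices)
})

test_that("a reduced-scale replica runs the whole pipeline end to end", {
  rep <- make_study_replica(seed = 82, n_nodes = 16)
  Xd <- cohort_edge_matrix(rep$discovery)
  yd <- score_cohort_behavior(rep$discovery)$value
  fit <- nested_cv_discover(Xd, yd, grid = list(k = c(5, 10), alpha = c(0.1, 1)))
  Xv <- rbind(cohort_edge_matrix(rep$validation1),
              cohort_edge_matrix(rep$validation2))
  yv <- c(score_cohort_behavior(rep$validation1)$value,
          score_cohort_behavior(rep$validation2)$value)
  pred <- predict(fit$model, Xv)
  metrics <- evaluate_predictions(pred, yv,
                                  cohort = rep(c("v1", "v2"), c(26, 23)),
                                  n_boot = 200, seed = 83)
  expect_equal(nrow(metrics), 3L)
  expect_true(all(is.finite(metrics$r)))
  expect_true(all(metrics$rmse > 0))
})

test_that("cohorts round-trip through the delimited-text layout", {
  spec <- cohort_spec(n_subjects = 4, n_nodes = 6, n_timepoints = 30,
                      true_edges = 2, effect_size = 0.4, seed = 84,
                      label = "io")
  coh <- generate_cohort(spec)
  dir <- tempfile("cohort")
  write_cohort(coh, dir)
  ts <- read_timeseries_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(names(ts), names(coh$timeseries))
  expect_equal(ts[[2]], coh$timeseries[[2]], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(colnames(ts[[1]]), colnames(coh$timeseries[[1]]))
})
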