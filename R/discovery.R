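#' Default hyperparameter grid for model discovery
#'
#' `k` is the number of edges kept by univariate selection, `alpha` the
#' L2 (ridge) penalty. Both lists are fully configurable; the defaults
#' span sparse to moderately dense models and penalties from nearly
#' unregularized (0.001) to strongly shrunk (10).
#'
#' @param k Candidate numbers of selected edges (positive integers).
#' @param alpha Candidate ridge penalties (non-negative).
#' @return List with sorted, validated `k` and `alpha` vectors.
#' @export
default_grid <- function(k = c(5, 10, 25, 50, 100),
                         alpha = c(0.001, 0.01, 0.1, 1, 10)) {
  k <- sort(unique(as.integer(k)))
  alpha <- sort(unique(as.numeric(alpha)))
  if (length(k) == 0 || any(k < 1)) abort("'k' values must be positive integers")
  if (length(alpha) == 0 || any(alpha < 0)) abort("'alpha' values must be >= 0")
  list(k = k, alpha = alpha)
}

#' k-best univariate edge selection
#'
#' Ranks features by the absolute Pearson correlation with the target
#' (the same ordering as the univariate regression F statistic) and
#' returns the top `k`. Constant features score 0 and are never selected
#' ahead of any feature with a positive score; exact score ties break
#' toward the lower column index.
#'
#' @param X Numeric subjects-by-features matrix.
#' @param y Numeric target vector (must not be constant).
#' @param k Number of features to keep (`1 <= k <= ncol(X)`).
#' @return Sorted (ascending) 1-based column indices of the selected
#'   features.
#' @export
kbest_select <- function(X, y, k) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  check_numeric_vector(y, "y", min_len = 2L)
  if (sd(y) == 0) abort("target 'y' is constant; univariate scores undefined")
  if (k < 1 || k > ncol(X)) abort("'k' must be in [1, ncol(X)]")
  score <- suppressWarnings(abs(as.numeric(cor(X, y))))
  score[is.na(score)] <- 0
  ord <- order(-score, seq_along(score))
  sort(ord[seq_len(k)])
}

#' Ridge regression with unpenalized intercept
#'
#' Minimizes `||y - X w - b||^2 + alpha * ||w||^2` with the intercept `b`
#' left out of the penalty. Solved by QR factorization of the
#' `sqrt(alpha)`-augmented design, which is numerically stabler than
#' forming the normal equations. With `alpha = 0` on a full-rank design
#' this is ordinary least squares; as `alpha` grows, weights shrink to 0
#' and the intercept tends to `mean(y)`.
#'
#' @param X Numeric predictor matrix (rows >= 2).
#' @param y Numeric response.
#' @param alpha Non-negative L2 penalty.
#' @param center Center `X` and `y` before fitting (default). With
#'   `center = FALSE` inputs are taken as already centered and the
#'   intercept is 0.
#' @return List with `weights` and `intercept`.
#' @export
fit_ridge <- function(X, y, alpha, center = TRUE) {
  stopifnot(is.matrix(X), nrow(X) == length(y), nrow(X) >= 2)
  check_numeric_vector(y, "y", min_len = 2L)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0) {
    abort("'alpha' must be a single non-negative number")
  }
  p <- ncol(X)
  if (center) {
    xm <- colMeans(X)
    xc <- sweep(X, 2, xm)
    ym <- mean(y)
    yc <- y - ym
  } else {
    xc <- X; yc <- y
  }
  aug_x <- rbind(xc, diag(sqrt(alpha), p))
  aug_y <- c(yc, numeric(p))
  w <- qr.coef(qr(aug_x), aug_y)
  w[is.na(w)] <- 0
  list(weights = unname(w),
       intercept = if (center) ym - sum(xm * w) else 0)
}

#' Discover a predictive model under nested LOPO cross-validation
#'
#' The outer loop leaves one participant out at a time; for each outer
#' fold, an inner leave-one-out loop over the remaining participants
#' scores every `(k, alpha)` combination of the grid by mean squared
#' error and the winning combination (ties: smaller `k`, then larger
#' `alpha`) is refitted on the outer-training set to predict the held-out
#' participant. Univariate selection and feature standardization are
#' recomputed inside every training partition, so no information from a
#' held-out participant leaks into its fold's model. The concatenated
#' outer predictions give the internal performance estimate; the final
#' model applies the inner criterion to the full sample and is fitted on
#' all participants.
#'
#' @param X Numeric subjects-by-edges matrix (canonical edge ordering;
#'   see [vectorize_connectivity()]).
#' @param y Numeric target (differential valence change), one value per
#'   row of `X`.
#' @param grid Hyperparameter grid from [default_grid()].
#' @param n_nodes Number of connectome nodes; inferred from `ncol(X)`
#'   (or the matrix's `n_nodes` attribute) when `NULL`.
#' @param target_name Label stored in the frozen model.
#' @param scale_features Divide each selected feature by its
#'   training-partition standard deviation in addition to centering.
#'   Defaults to `FALSE`: partial-correlation edges share a natural
#'   common scale, and per-feature scaling amplifies estimation noise in
#'   low-variance edges at the expense of external generalization.
#' @return List with components `model` (a `frozen_model`: selected
#'   0-based edge indices, weights, intercept, `k`, `alpha`,
#'   standardization constants, ordering tag) and `report` (outer
#'   predictions, per-fold hyperparameters and fold models, internal
#'   Pearson `r` and `r_squared`).
#' @export
nested_cv_discover <- function(X, y, grid = default_grid(), n_nodes = NULL,
                               target_name = "dvc", scale_features = FALSE) {
  stopifnot(is.matrix(X))
  check_numeric_vector(y, "y", min_len = 2L)
  if (nrow(X) != length(y)) abort("nrow(X) must equal length(y)")
  if (nrow(X) < 10) abort("need at least 10 subjects for nested LOPO discovery")
  if (anyNA(X)) abort("'X' contains missing values")
  if (sd(y) == 0) abort("target 'y' is constant")
  grid <- default_grid(grid$k, grid$alpha)
  grid$k <- grid$k[grid$k <= ncol(X)]
  if (length(grid$k) == 0) abort("all grid k values exceed ncol(X)")
  if (is.null(n_nodes)) {
    n_nodes <- attr(X, "n_nodes")
    if (is.null(n_nodes)) {
      n_nodes <- tryCatch(nodes_from_edges(ncol(X)), error = function(e) NA_integer_)
    }
  }
  fit <- cpp_nested_cv(X, y, as.integer(grid$k), as.numeric(grid$alpha),
                       keep_fold_models = TRUE,
                       scale_features = scale_features)
  outer_pred <- as.numeric(fit$outer_pred)
  r_internal <- if (sd(outer_pred) > 0) cor(outer_pred, y) else 0
  model <- new_frozen_model(
    selected_edges = as.integer(fit$selected),
    weights = as.numeric(fit$weights),
    intercept = fit$intercept,
    k = fit$final_k, alpha = fit$final_alpha,
    center = as.numeric(fit$center), scale = as.numeric(fit$scale),
    n_nodes = as.integer(n_nodes), target_name = target_name)
  report <- list(
    outer_pred = outer_pred,
    fold_k = as.integer(fit$fold_k),
    fold_alpha = as.numeric(fit$fold_alpha),
    fold_models = fit$fold_models,
    r_internal = r_internal,
    r_squared_internal = r_internal^2,
    n = nrow(X), grid = grid)
  list(model = model, report = report)
}

#' Permutation test of internal predictive performance
#'
#' Permutes the target vector `B` times (subjects exchangeable under the
#' null) and reruns the complete nested cross-validation internal
#' performance estimate for each permutation. The p-value is
#' `(1 + #\{null r >= observed r\}) / (B + 1)`, so its floor is
#' `1 / (B + 1)` and its ceiling 1.
#'
#' @inheritParams nested_cv_discover
#' @param B Number of permutations (>= 99).
#' @param seed Integer seed making the permutations reproducible.
#' @return List with `p`, `observed_r`, `null_r` (length `B`), and `B`.
#' @export
permutation_test <- function(X, y, grid = default_grid(), B = 999, seed = 1L,
                             scale_features = FALSE) {
  if (B < 99) abort("B must be >= 99 for meaningful permutation resolution")
  grid <- default_grid(grid$k, grid$alpha)
  grid$k <- grid$k[grid$k <= ncol(X)]
  if (length(grid$k) == 0) abort("all grid k values exceed ncol(X)")
  fit <- cpp_nested_cv(X, y, as.integer(grid$k), as.numeric(grid$alpha),
                       FALSE, scale_features)
  outer_pred <- as.numeric(fit$outer_pred)
  observed <- if (sd(outer_pred) > 0) cor(outer_pred, y) else 0
  yperm <- with_seed(seed, {
    vapply(seq_len(B), function(b) y[sample.int(length(y))],
           numeric(length(y)))
  })
  null_r <- as.numeric(cpp_perm_null(X, yperm, as.integer(grid$k),
                                     as.numeric(grid$alpha), scale_features))
  p <- (1 + sum(null_r >= observed)) / (B + 1)
  list(p = p, observed_r = observed, null_r = null_r, B = B)
}
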