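#' Standardize region timeseries
#'
#' Z-scores every column (region signal) of a timepoints-by-regions
#' matrix to mean 0 and unit (sample) standard deviation. Idempotent up
#' to numerical tolerance.
#'
#' @param ts Numeric T-by-M matrix; column names are node labels.
#' @return Matrix of the same shape with standardized columns.
#' @export
standardize_timeseries <- function(ts) {
  if (!is.matrix(ts) || !is.numeric(ts)) abort("'ts' must be a numeric matrix")
  if (anyNA(ts)) abort("timeseries contain missing values")
  if (nrow(ts) < 2) abort("need at least 2 timepoints")
  sds <- apply(ts, 2, sd)
  if (any(sds == 0)) {
    lab <- colnames(ts)[which(sds == 0)[1]]
    if (is.null(lab)) lab <- as.character(which(sds == 0)[1])
    abort("constant signal in node '%s'; cannot standardize", lab)
  }
  scale(ts, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Partial-correlation connectivity matrix
#'
#' Estimates the M-by-M partial-correlation matrix of a subject's region
#' timeseries: entry (i, j) is the correlation between nodes i and j
#' after removing the linear influence of all other nodes, computed from
#' the precision matrix P as `-P_ij / sqrt(P_ii * P_jj)`; the diagonal is
#' set to 1.
#'
#' With `shrinkage = "auto"` (default) the covariance is regularized with
#' an analytic Ledoit-Wolf shrinkage toward a scaled identity before
#' inversion, the standard stabilization when the number of nodes is
#' comparable to the number of timepoints. `shrinkage = "none"` inverts
#' the sample covariance directly (errors if singular); a numeric value
#' in `[0, 1]` fixes the shrinkage intensity.
#'
#' @param ts Numeric T-by-M timeseries matrix (standardized or not;
#'   partial correlations are scale-invariant, but see
#'   [standardize_timeseries()] for the canonical preprocessing).
#' @param shrinkage `"auto"`, `"none"`, or a number in `[0, 1]`.
#' @return Symmetric M-by-M matrix with unit diagonal, off-diagonal
#'   entries in `[-1, 1]`; node labels carried over as dimnames.
#' @export
partial_correlation <- function(ts, shrinkage = "auto") {
  if (!is.matrix(ts) || !is.numeric(ts)) abort("'ts' must be a numeric matrix")
  if (anyNA(ts)) abort("timeseries contain missing values")
  n <- nrow(ts); m <- ncol(ts)
  if (n < 2) abort("need at least 2 timepoints")
  xc <- scale(ts, center = TRUE, scale = FALSE)
  s <- crossprod(xc) / n
  if (identical(shrinkage, "none")) {
    p <- tryCatch(solve(s), error = function(e) NULL)
    if (is.null(p) || kappa(s, exact = FALSE) > 1e12) {
      abort(paste("sample covariance is singular or ill-conditioned;",
                  "use shrinkage = 'auto' or a numeric shrinkage intensity"))
    }
  } else {
    rho <- if (identical(shrinkage, "auto")) {
      ledoit_wolf_intensity(xc, s)
    } else {
      if (!is.numeric(shrinkage) || shrinkage < 0 || shrinkage > 1) {
        abort("'shrinkage' must be \"auto\", \"none\", or a number in [0, 1]")
      }
      shrinkage
    }
    mu <- mean(diag(s))
    s_shrunk <- (1 - rho) * s
    diag(s_shrunk) <- diag(s_shrunk) + rho * mu
    p <- solve(s_shrunk)
  }
  d <- 1 / sqrt(diag(p))
  pc <- -p * tcrossprod(d)
  pc <- (pc + t(pc)) / 2
  diag(pc) <- 1
  pc[pc > 1] <- 1; pc[pc < -1] <- -1
  dimnames(pc) <- list(colnames(ts), colnames(ts))
  pc
}

# analytic (Ledoit-Wolf) shrinkage intensity toward mu*I;
# xc: centered data (n x p), s: crossprod(xc)/n
ledoit_wolf_intensity <- function(xc, s) {
  n <- nrow(xc); p <- ncol(xc)
  mu <- mean(diag(s))
  d2 <- sum((s - diag(mu, p))^2) / p
  if (d2 < .Machine$double.eps) return(0)
  # E||x_t x_t' - S||_F^2 averaged: sum_t ||x_t||^4 - n ||S||_F^2
  b2 <- (sum(rowSums(xc^2)^2) - n * sum(s^2)) / (n^2 * p)
  b2 <- min(max(b2, 0), d2)
  b2 / d2
}

#' Vectorize a connectivity matrix into the canonical edge vector
#'
#' Extracts the strict upper triangle in row-major node order
#' ((0,1), (0,2), ..., (0,M-1), (1,2), ...), yielding the length
#' `M*(M-1)/2` edge vector every model in this package consumes. The
#' result carries `n_nodes` and `ordering_version` attributes.
#'
#' @param cm Symmetric numeric matrix (asymmetry beyond `tol` errors).
#' @param tol Symmetry tolerance.
#' @return Numeric edge vector of length `M*(M-1)/2`.
#' @seealso [devectorize_connectivity()], [edge_to_nodes()]
#' @export
vectorize_connectivity <- function(cm, tol = 1e-8) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) abort("'cm' must be a square matrix")
  if (max(abs(cm - t(cm))) > tol) abort("matrix is not symmetric within tolerance")
  m <- nrow(cm)
  v <- t(cm)[lower.tri(cm)] # row-major upper triangle
  structure(v, n_nodes = m, ordering_version = EDGE_ORDERING_VERSION)
}

#' Rebuild a symmetric matrix from a canonical edge vector
#'
#' Inverse of [vectorize_connectivity()]; the diagonal is set to `diag`.
#'
#' @param v Edge vector of length `M*(M-1)/2`.
#' @param diag Diagonal value (default 1).
#' @return Symmetric M-by-M matrix.
#' @export
devectorize_connectivity <- function(v, diag = 1) {
  m <- nodes_from_edges(length(v))
  cm <- matrix(0, m, m)
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE] # row-major
  cm[idx] <- v
  cm <- cm + t(cm)
  diag(cm) <- diag
  cm
}

#' Map edge indices to node pairs (and back)
#'
#' Edge indices follow the canonical strict-upper-triangle row-major
#' ordering and are 0-based, matching the serialized model format: edge 0
#' is nodes (0, 1) and edge `M*(M-1)/2 - 1` is nodes (M-2, M-1).
#'
#' @param edge_index Integer vector of 0-based edge indices.
#' @param n_nodes Number of nodes M.
#' @return For `edge_to_nodes`, a 2-column matrix of 0-based node indices
#'   `(i, j)` with `i < j`; for `nodes_to_edge`, 0-based edge indices.
#' @examples
#' edge_to_nodes(7502, 123) # nodes 121, 122
#' @export
edge_to_nodes <- function(edge_index, n_nodes) {
  e <- n_edges(n_nodes)
  if (any(edge_index < 0 | edge_index >= e)) {
    abort("edge index out of range [0, %d)", e)
  }
  k <- as.numeric(edge_index)
  i <- floor(((2 * n_nodes - 1) - sqrt((2 * n_nodes - 1)^2 - 8 * k)) / 2)
  # guard against floating-point boundary errors
  first <- i * (2 * n_nodes - i - 1) / 2
  i <- ifelse(first > k, i - 1, i)
  first <- i * (2 * n_nodes - i - 1) / 2
  j <- i + 1 + (k - first)
  cbind(i = as.integer(i), j = as.integer(j))
}

#' @rdname edge_to_nodes
#' @param i,j 0-based node indices with `i < j`.
#' @export
nodes_to_edge <- function(i, j, n_nodes) {
  if (any(i >= j)) abort("require i < j (0-based node indices)")
  if (any(i < 0 | j >= n_nodes)) abort("node index out of range")
  as.integer(i * (2 * n_nodes - i - 1) / 2 + (j - i - 1))
}

#' Edge matrix for a set of subjects
#'
#' Convenience wrapper running the canonical per-subject pipeline
#' (standardize, partial correlation, vectorize) over a list of
#' timeseries matrices, returning the subjects-by-edges feature matrix
#' used for model discovery and validation.
#'
#' @param ts_list Named list of T-by-M timeseries matrices.
#' @param shrinkage Passed to [partial_correlation()].
#' @return Numeric n-by-`M*(M-1)/2` matrix with subject ids as rownames
#'   and `n_nodes`/`ordering_version` attributes.
#' @export
edge_matrix <- function(ts_list, shrinkage = "auto") {
  stopifnot(is.list(ts_list), length(ts_list) >= 1)
  rows <- lapply(ts_list, function(ts) {
    vectorize_connectivity(partial_correlation(standardize_timeseries(ts),
                                               shrinkage = shrinkage))
  })
  m <- attr(rows[[1]], "n_nodes")
  x <- do.call(rbind, lapply(rows, as.numeric))
  rownames(x) <- names(ts_list)
  structure(x, n_nodes = m, ordering_version = EDGE_ORDERING_VERSION)
}
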