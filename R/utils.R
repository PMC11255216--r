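#' Canonical edge-ordering tag
#'
#' Identifies the strict-upper-triangle, row-major, 0-based edge ordering
#' used for every vectorized connectome and serialized model in this
#' package. Stored alongside models and edge vectors so that a model is
#' never applied to edges laid out under a different convention.
#'
#' @format A length-one character string.
#' @export
EDGE_ORDERING_VERSION <- "utri-rowmajor-0based/v1"

#' Number of unique edges among M nodes
#'
#' @param n_nodes Number of nodes (regions) in the connectome.
#' @return Integer, `n_nodes * (n_nodes - 1) / 2`.
#' @examples
#' n_edges(123) # 7503
#' @export
n_edges <- function(n_nodes) {
  stopifnot(is.numeric(n_nodes), n_nodes >= 2)
  as.integer(n_nodes * (n_nodes - 1) / 2)
}

# infer node count from an edge-vector length; error if not triangular
nodes_from_edges <- function(n_edge) {
  m <- (1 + sqrt(1 + 8 * n_edge)) / 2
  if (abs(m - round(m)) > 1e-8) {
    stop("edge vector length ", n_edge,
         " is not M*(M-1)/2 for any integer M", call. = FALSE)
  }
  as.integer(round(m))
}

# evaluate `expr` under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is untouched. seed = NULL runs unseeded.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# stop() with sprintf-style formatting, no call in message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_numeric_vector <- function(x, name, min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len) {
    abort("'%s' must be a numeric vector of length >= %d", name, min_len)
  }
  if (anyNA(x)) abort("'%s' contains missing values", name)
  invisible(x)
}

# percentile bootstrap CI for a statistic over rows of resampled indices
boot_ci <- function(n, stat_fn, n_boot, level, seed) {
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  with_seed(seed, {
    stats_b <- vapply(seq_len(n_boot), function(b) {
      stat_fn(sample.int(n, n, replace = TRUE))
    }, numeric(1))
    unname(quantile(stats_b, probs, na.rm = TRUE))
  })
}

# one-tailed (H1: r > 0) p-value for a Pearson correlation
cor_p_one_tailed <- function(r, n) {
  if (n < 3) return(NA_real_)
  t <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  pt(t, df = n - 2, lower.tail = FALSE)
}
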