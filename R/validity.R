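#' Conditional-independence (partial generalization / confounder) test
#'
#' Tests whether model predictions carry association with a third
#' variable `c` beyond what the shared association of both with the
#' target `y` explains. The statistic is the absolute partial Pearson
#' correlation of `yhat` and `c` given `y`; its null distribution is
#' built by conditional permutations of `c` that preserve the empirical
#' dependence of `c` on `y`, so the null hypothesis is conditional
#' independence (`yhat` independent of `c` given `y`), not marginal
#' independence.
#'
#' Two permutation schemes are available. `"bins"` (default,
#' assumption-light): subjects are ranked by `y` and cut into
#' `floor(sqrt(n))` nearly equal strata (strata smaller than 3 are merged
#' with a neighbor) and `c` is permuted within strata. `"residual"`
#' (model-based): a spline regression of `c` on `y` is fitted, residuals
#' are permuted, and fitted values added back.
#'
#' A rejection (`p < alpha`) means the predictions *generalize* to `c`
#' (for a convergent validator) or are *biased* by it (for a confounder).
#'
#' @param y Observed target vector.
#' @param yhat Model predictions (same length).
#' @param c Validator/confounder vector (same length, not constant).
#' @param B Number of conditional permutations (>= 99).
#' @param seed Integer seed.
#' @param scheme `"bins"` or `"residual"`.
#' @param validator_name Label carried into the result.
#' @return Object of class `conditional_test_result`: the three marginal
#'   squared correlations (`r2_target_validator`,
#'   `r2_prediction_validator`, `r2_target_prediction`), the observed
#'   statistic, `p_conditional`, `n_permutations`, and the scheme used.
#' @export
partial_generalization_test <- function(y, yhat, c, B = 1000, seed = 1L,
                                        scheme = c("bins", "residual"),
                                        validator_name = "validator") {
  scheme <- match.arg(scheme)
  check_numeric_vector(y, "y"); check_numeric_vector(yhat, "yhat")
  check_numeric_vector(c, "c")
  n <- length(y)
  if (length(yhat) != n || length(c) != n) abort("y, yhat, c must have equal length")
  if (n < 10) abort("need at least 10 subjects")
  if (B < 99) abort("B must be >= 99")
  if (sd(y) == 0) abort("'y' is constant")
  if (sd(c) == 0) abort("'%s' is constant", validator_name)
  if (sd(yhat) == 0) abort("'yhat' is constant")

  r_yc <- cor(y, c); r_hc <- cor(yhat, c); r_yh <- cor(y, yhat)
  observed <- abs_pcor(r_hc, r_yc, r_yh)

  cperm <- with_seed(seed, {
    if (scheme == "bins") {
      permute_within_strata(c, y_strata(y), B)
    } else {
      permute_residuals(c, y, B)
    }
  })
  # vectorized null statistics over all B permuted copies of c
  r_yc_b <- as.numeric(cor(y, cperm))
  r_hc_b <- as.numeric(cor(yhat, cperm))
  null_stat <- abs_pcor(r_hc_b, r_yc_b, r_yh)
  p <- (1 + sum(null_stat >= observed)) / (B + 1)

  structure(list(validator_name = validator_name,
                 r2_target_validator = r_yc^2,
                 r2_prediction_validator = r_hc^2,
                 r2_target_prediction = r_yh^2,
                 statistic = observed,
                 p_conditional = p,
                 n_permutations = B,
                 null_statistics = null_stat,
                 scheme = scheme, n = n),
            class = "conditional_test_result")
}

# |partial correlation of (a, b | z)| from the three pairwise correlations
abs_pcor <- function(r_ab, r_az, r_bz) {
  den <- sqrt(pmax(1 - r_az^2, .Machine$double.eps) *
              pmax(1 - r_bz^2, .Machine$double.eps))
  abs((r_ab - r_az * r_bz) / den)
}

# rank y and cut into floor(sqrt(n)) nearly equal strata; strata smaller
# than min_size are merged with the previous one
y_strata <- function(y, min_size = 3L) {
  n <- length(y)
  q <- max(1L, floor(sqrt(n)))
  sizes <- rep(n %/% q, q)
  if (n %% q > 0) sizes[seq_len(n %% q)] <- sizes[seq_len(n %% q)] + 1L
  while (length(sizes) > 1 && min(sizes) < min_size) {
    i <- which.min(sizes)
    j <- if (i == 1) 2L else i - 1L
    sizes[j] <- sizes[j] + sizes[i]
    sizes <- sizes[-i]
  }
  stratum <- rep(seq_along(sizes), sizes)
  stratum[order(order(y))] # map back from sorted order to original rows
}

permute_within_strata <- function(c, stratum, B) {
  n <- length(c)
  out <- matrix(NA_real_, n, B)
  for (s in unique(stratum)) {
    rows <- which(stratum == s)
    if (length(rows) == 1) {
      out[rows, ] <- c[rows]
    } else {
      for (b in seq_len(B)) out[rows, b] <- c[rows[sample.int(length(rows))]]
    }
  }
  out
}

permute_residuals <- function(c, y, B) {
  fitted_c <- if (length(unique(y)) >= 10) {
    sp <- smooth.spline(y, c, cv = FALSE)
    predict(sp, y)$y
  } else {
    stats::fitted(lm(c ~ y))
  }
  res <- c - fitted_c
  vapply(seq_len(B), function(b) fitted_c + res[sample.int(length(res))],
         numeric(length(c)))
}

#' @export
print.conditional_test_result <- function(x, ...) {
  cat(sprintf(
    "Conditional independence test for '%s' (scheme: %s, B = %d)\n",
    x$validator_name, x$scheme, x$n_permutations))
  cat(sprintf("  R2 target~validator:     %5.1f%%\n", 100 * x$r2_target_validator))
  cat(sprintf("  R2 prediction~validator: %5.1f%%\n", 100 * x$r2_prediction_validator))
  cat(sprintf("  R2 target~prediction:    %5.1f%%\n", 100 * x$r2_target_prediction))
  cat(sprintf("  p (conditional):         %.4g\n", x$p_conditional))
  invisible(x)
}

#' Run a battery of validity and confounder tests
#'
#' Applies [partial_generalization_test()] to every named validator
#' column and tabulates the results in the conventional layout: the
#' marginal squared correlation of each validator with the target and
#' with the prediction (both in percent), and the conditional
#' permutation p-value. No multiplicity correction is applied by default
#' (each validator answers its own question); `adjust = "BH"` adds a
#' Benjamini-Hochberg column.
#'
#' @inheritParams partial_generalization_test
#' @param validators Named list or data frame of numeric validator /
#'   confounder vectors (duplicate names are an error). Validators with
#'   missing values raise an error; handle missingness explicitly
#'   upstream.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame with one row per validator.
#' @export
run_validity_battery <- function(y, yhat, validators, B = 1000, seed = 1L,
                                 scheme = c("bins", "residual"),
                                 adjust = c("none", "BH")) {
  scheme <- match.arg(scheme); adjust <- match.arg(adjust)
  validators <- as.list(validators)
  if (length(validators) == 0) {
    return(data.frame(validator = character(0), r2_target_pct = numeric(0),
                      r2_prediction_pct = numeric(0), p_conditional = numeric(0),
                      n_permutations = integer(0)))
  }
  if (is.null(names(validators)) || anyDuplicated(names(validators))) {
    abort("validators must have unique names")
  }
  rows <- lapply(names(validators), function(nm) {
    res <- partial_generalization_test(y, yhat, validators[[nm]], B = B,
                                       seed = seed, scheme = scheme,
                                       validator_name = nm)
    data.frame(validator = nm,
               r2_target_pct = 100 * res$r2_target_validator,
               r2_prediction_pct = 100 * res$r2_prediction_validator,
               p_conditional = res$p_conditional,
               n_permutations = res$n_permutations,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adjusted <- p.adjust(out$p_conditional, "BH")
  out
}
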