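#' External-validation performance metrics
#'
#' Correlates model predictions with observed learning scores and
#' reports, per cohort and pooled: Pearson `r` with a one-tailed p-value
#' (H1: r > 0, t-transform with n-2 df), a percentile-bootstrap 90%
#' confidence interval for `r`, explained variance as the squared
#' correlation (`r_squared`; the conventional "% variance explained" for
#' correlation-scale effects), the coefficient of determination
#' (`r2_cod = 1 - SS_res/SS_tot`, which additionally penalizes
#' miscalibration), the root mean squared error in rating-scale units,
#' and the observed range.
#'
#' @param predicted Numeric predictions; if named, names are matched
#'   against `observed`.
#' @param observed Numeric observed values (same length; if both are
#'   named the names must agree as sets and are used for alignment).
#' @param cohort Optional cohort label per subject; metrics are then
#'   computed per cohort and pooled.
#' @param n_boot Bootstrap resamples for the CI (default 5000).
#' @param ci_level Confidence level of the bootstrap interval (0.90,
#'   matching the reporting convention for external validation).
#' @param seed Integer seed for the bootstrap.
#' @return Data frame, one row per cohort plus `"pooled"` (or a single
#'   `"all"` row when `cohort` is `NULL`).
#' @export
evaluate_predictions <- function(predicted, observed, cohort = NULL,
                                 n_boot = 5000, ci_level = 0.90, seed = 1L) {
  check_numeric_vector(predicted, "predicted", 3L)
  check_numeric_vector(observed, "observed", 3L)
  if (!is.null(names(predicted)) && !is.null(names(observed))) {
    missing_ids <- setdiff(names(predicted), names(observed))
    extra_ids <- setdiff(names(observed), names(predicted))
    if (length(missing_ids) || length(extra_ids)) {
      abort("subject ids do not match (only in predictions: %s; only in observations: %s)",
            paste(missing_ids, collapse = ","), paste(extra_ids, collapse = ","))
    }
    observed <- observed[names(predicted)]
    if (!is.null(cohort) && !is.null(names(cohort))) {
      cohort <- cohort[names(predicted)]
    }
  }
  if (length(predicted) != length(observed)) {
    abort("'predicted' and 'observed' differ in length")
  }
  one <- function(p, o, label) {
    n <- length(p)
    if (sd(p) == 0) abort("predictions have zero variance in '%s'; r undefined", label)
    if (sd(o) == 0) abort("observations have zero variance in '%s'; r undefined", label)
    r <- cor(p, o)
    ci <- boot_ci(n, function(idx) {
      if (sd(p[idx]) == 0 || sd(o[idx]) == 0) return(NA_real_)
      cor(p[idx], o[idx])
    }, n_boot, ci_level, seed)
    data.frame(
      cohort = label, n = n, r = r,
      p_one_tailed = cor_p_one_tailed(r, n),
      ci_lo = ci[1], ci_hi = ci[2],
      r_squared = r^2,
      r2_cod = 1 - sum((o - p)^2) / sum((o - mean(o))^2),
      rmse = sqrt(mean((o - p)^2)),
      obs_min = min(o), obs_max = max(o),
      stringsAsFactors = FALSE)
  }
  if (is.null(cohort)) return(one(predicted, observed, "all"))
  stopifnot(length(cohort) == length(predicted))
  rows <- lapply(unique(as.character(cohort)), function(cl) {
    sel <- cohort == cl
    one(predicted[sel], observed[sel], cl)
  })
  rbind(do.call(rbind, rows), one(predicted, observed, "pooled"))
}
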