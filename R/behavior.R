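#' Differential valence change (DVC)
#'
#' Scores pain- (or tone-) related learning for each subject from
#' conditioning valence ratings:
#' `DVC = (CS+_acq - CS+_hab) - (CS-_acq - CS-_hab)`,
#' i.e. how much the unpleasantness of the reinforced cue grew over
#' acquisition, relative to the never-reinforced safety cue. Positive
#' values indicate learning; the score is invariant to adding a constant
#' to all four ratings.
#'
#' Only the habituation and end-of-acquisition ratings enter the score;
#' other phases present in `ratings` are ignored. If several acquisition
#' ratings are present (phases ordered by the factor/character ordering of
#' `acq_phase`), supply the end-of-acquisition rows as `acquisition_end`.
#'
#' @param ratings Data frame with columns `subject_id`, `condition`
#'   (`"CS_plus_pain"`, `"CS_plus_tone"`, `"CS_minus"`), `phase`
#'   (`"habituation"`, `"acquisition_end"`, ...) and `value` (0-100).
#' @param modality `"pain"` or `"tone"`: which CS+ condition is scored.
#' @return Data frame with columns `subject_id`, `modality`, `value`.
#' @examples
#' r <- data.frame(
#'   subject_id = "s1",
#'   condition  = c("CS_plus_pain", "CS_plus_pain", "CS_minus", "CS_minus"),
#'   phase      = c("habituation", "acquisition_end", "habituation", "acquisition_end"),
#'   value      = c(50, 80, 50, 55))
#' compute_dvc(r, "pain")$value # 25
#' @export
compute_dvc <- function(ratings, modality = c("pain", "tone")) {
  modality <- match.arg(modality)
  req <- c("subject_id", "condition", "phase", "value")
  if (!is.data.frame(ratings) || !all(req %in% names(ratings))) {
    abort("'ratings' must be a data frame with columns %s",
          paste(req, collapse = ", "))
  }
  validate_ratings(ratings)
  cs_plus <- if (modality == "pain") "CS_plus_pain" else "CS_plus_tone"
  subjects <- unique(as.character(ratings$subject_id))
  value <- vapply(subjects, function(s) {
    cell <- function(cond, phase) {
      v <- ratings$value[ratings$subject_id == s &
                         ratings$condition == cond &
                         ratings$phase == phase]
      if (length(v) == 0) {
        abort("subject '%s': missing rating for cell (%s, %s)", s, cond, phase)
      }
      v[[1]]
    }
    (cell(cs_plus, "acquisition_end") - cell(cs_plus, "habituation")) -
      (cell("CS_minus", "acquisition_end") - cell("CS_minus", "habituation"))
  }, numeric(1))
  data.frame(subject_id = subjects, modality = modality,
             value = unname(value), stringsAsFactors = FALSE)
}

validate_ratings <- function(ratings) {
  if (anyNA(ratings$value)) abort("ratings contain missing values")
  bad <- ratings$value < 0 | ratings$value > 100
  if (any(bad)) {
    abort("rating out of the 0-100 scale for subject '%s' (%s, %s): %g",
          ratings$subject_id[bad][1], ratings$condition[bad][1],
          ratings$phase[bad][1], ratings$value[bad][1])
  }
  key <- paste(ratings$subject_id, ratings$condition, ratings$phase)
  if (anyDuplicated(key)) {
    abort("duplicated (subject, condition, phase) cell: %s",
          key[duplicated(key)][1])
  }
  invisible(ratings)
}

#' Harmonize ratings measured on alternate scale anchors
#'
#' Maps a 0-100 rating collected with "not unpleasant at all" / "very
#' unpleasant" anchors onto the discovery-study scale, whose anchors run
#' from "very pleasant" (0) through neutral (50) to "very unpleasant"
#' (100): `value / 2 + 50`. The transform is affine and monotone, mapping
#' 0 to 50 and 100 to 100. It is applied only when a cohort is explicitly
#' flagged as using the alternate anchors; nothing is auto-detected.
#'
#' @param value Numeric vector of raw ratings in `[0, 100]`.
#' @return Harmonized ratings in `[50, 100]`.
#' @examples
#' harmonize_scale(c(0, 40, 100)) # 50 70 100
#' @export
harmonize_scale <- function(value) {
  check_numeric_vector(value, "value")
  if (any(value < 0 | value > 100)) {
    abort("raw rating out of the 0-100 scale: %g",
          value[value < 0 | value > 100][1])
  }
  value / 2 + 50
}

#' Motion-based quality-control exclusion
#'
#' Applies the pre-registered head-motion exclusion rule: a subject is
#' excluded when mean framewise displacement exceeds `mean_fd_limit`
#' (default 0.15 mm) or when more than `scrub_limit_pct` percent of
#' volumes were scrubbed (default 25). Both thresholds are configurable
#' (set them to `Inf`/100 to drop motion exclusion entirely).
#'
#' @param motion Data frame with columns `subject_id`, `mean_fd` and
#'   `pct_scrubbed` (additional motion summaries are carried through
#'   untouched).
#' @param mean_fd_limit Mean-FD threshold in mm.
#' @param scrub_limit_pct Scrubbed-volume threshold in percent.
#' @return Data frame `subject_id`, `exclude` (logical), `reason`
#'   (`NA` for kept subjects).
#' @examples
#' qc_exclude(data.frame(subject_id = "s1", mean_fd = 0.16, pct_scrubbed = 5))
#' @export
qc_exclude <- function(motion, mean_fd_limit = 0.15, scrub_limit_pct = 25) {
  req <- c("subject_id", "mean_fd", "pct_scrubbed")
  if (!is.data.frame(motion) || !all(req %in% names(motion))) {
    abort("'motion' must be a data frame with columns %s",
          paste(req, collapse = ", "))
  }
  if (any(motion$mean_fd < 0, na.rm = TRUE) ||
      any(motion$pct_scrubbed < 0 | motion$pct_scrubbed > 100, na.rm = TRUE)) {
    abort("invalid motion summary: mean_fd must be >= 0, pct_scrubbed in [0, 100]")
  }
  fd_rule <- motion$mean_fd > mean_fd_limit
  scrub_rule <- motion$pct_scrubbed > scrub_limit_pct
  reason <- rep(NA_character_, nrow(motion))
  reason[scrub_rule] <- sprintf("pct_scrubbed > %g", scrub_limit_pct)
  reason[fd_rule] <- sprintf("mean_fd > %g", mean_fd_limit)
  reason[fd_rule & scrub_rule] <- sprintf(
    "mean_fd > %g; pct_scrubbed > %g", mean_fd_limit, scrub_limit_pct)
  data.frame(subject_id = motion$subject_id,
             exclude = fd_rule | scrub_rule,
             reason = reason, stringsAsFactors = FALSE)
}

#' Group-level learning summary with bootstrap confidence intervals
#'
#' Mean DVC per modality (and cohort, when a `cohort` column is present)
#' with a percentile bootstrap confidence interval over subject
#' resampling.
#'
#' @param dvc Data frame as returned by [compute_dvc()]; may carry an
#'   extra `cohort` column.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; the same seed reproduces the same interval.
#' @return Data frame with `modality` (and `cohort`), `n`, `mean`,
#'   `ci_lo`, `ci_hi`.
#' @export
summarize_learning <- function(dvc, n_boot = 5000, level = 0.95, seed = 1L) {
  stopifnot(is.data.frame(dvc), all(c("modality", "value") %in% names(dvc)))
  if (n_boot < 100) abort("n_boot must be >= 100")
  groups <- if ("cohort" %in% names(dvc)) {
    split(dvc, list(dvc$cohort, dvc$modality), drop = TRUE)
  } else {
    split(dvc, dvc$modality)
  }
  out <- lapply(names(groups), function(g) {
    v <- groups[[g]]$value
    if (length(v) < 2) abort("group '%s' has a single subject; CI undefined", g)
    ci <- boot_ci(length(v), function(idx) mean(v[idx]), n_boot, level, seed)
    res <- data.frame(modality = groups[[g]]$modality[1], n = length(v),
                      mean = mean(v), ci_lo = ci[1], ci_hi = ci[2],
                      stringsAsFactors = FALSE)
    if ("cohort" %in% names(dvc)) res <- cbind(cohort = groups[[g]]$cohort[1], res)
    res
  })
  do.call(rbind, out)
}
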