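#' Specification of a synthetic cohort
#'
#' Collects the generative parameters of a synthetic study cohort:
#' multi-subject region timeseries whose partial-correlation edges carry
#' a sparse linear coupling to a continuous behavioral target
#' (differential valence change, rating units), plus psychometric and
#' motion covariates and an optional confound channel with controllable
#' association to the target.
#'
#' Signal is injected in the precision domain: a shared base precision
#' matrix (identity plus small random symmetric off-diagonals,
#' diagonally loaded to guarantee positive definiteness) receives, for
#' each subject, perturbations of the `true_edges` precision entries with
#' across-subject standard deviation `coupling_sd`. These per-subject
#' latent edge strengths drive the target; partial correlation — the
#' pipeline's feature — is thus the natural readout of the planted
#' signal.
#'
#' @param n_subjects Number of subjects.
#' @param n_nodes Number of nodes M (122 regions + global signal = 123 at
#'   study scale; 20-30 keeps full-pipeline tests fast).
#' @param n_timepoints Resting-state timepoints T per subject.
#' @param true_edges Number K of edges truly coupled to the target.
#' @param coupling_sd Across-subject SD of the true-edge precision
#'   perturbations.
#' @param effect_size Fraction of target variance carried by the edges
#'   (`[0, 1)`); 0 generates null cohorts.
#' @param noise_sd Residual target SD in rating units.
#' @param confound_effect Correlation (population-scale) between the
#'   confound channel and the target; 0 gives an independent null
#'   confound.
#' @param intercept Mean of the target in rating units.
#' @param seed Integer seed; identical specs and seeds give bit-identical
#'   cohorts.
#' @param label Cohort label, used in subject ids.
#' @param scale_scheme `"default"` or `"vs2"` (ratings stored on the
#'   alternate 0-100 anchor scheme that [harmonize_scale()] maps back).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 25, n_nodes = 123, n_timepoints = 260,
                        true_edges = 5, coupling_sd = 0.25,
                        effect_size = 0.5, noise_sd = 16,
                        confound_effect = 0, intercept = 25, seed = 1L,
                        label = "cohort", scale_scheme = "default") {
  spec <- list(n_subjects = as.integer(n_subjects),
               n_nodes = as.integer(n_nodes),
               n_timepoints = as.integer(n_timepoints),
               true_edges = as.integer(true_edges),
               coupling_sd = coupling_sd, effect_size = effect_size,
               noise_sd = noise_sd, confound_effect = confound_effect,
               intercept = intercept, seed = as.integer(seed),
               label = label, scale_scheme = scale_scheme)
  if (spec$n_subjects < 2) abort("need at least 2 subjects")
  if (spec$n_nodes < 3) abort("need at least 3 nodes")
  if (spec$n_timepoints < 10) abort("need at least 10 timepoints")
  if (effect_size < 0 || effect_size >= 1) abort("effect_size must be in [0, 1)")
  if (spec$true_edges < 1 || spec$true_edges > n_edges(spec$n_nodes)) {
    abort("true_edges must be in [1, M*(M-1)/2]")
  }
  if (coupling_sd < 0 || noise_sd < 0) abort("sds must be >= 0")
  if (abs(confound_effect) > 1) abort("confound_effect must be in [-1, 1]")
  if (effect_size > 0 && coupling_sd == 0) {
    abort("effect_size > 0 requires coupling_sd > 0")
  }
  if (!scale_scheme %in% c("default", "vs2")) {
    abort("scale_scheme must be 'default' or 'vs2'")
  }
  structure(spec, class = "cohort_spec")
}

#' Shared generative template for a family of cohorts
#'
#' Builds the population-level structure — base precision matrix, true
#' edge set, generative weights, and target scaling — that discovery and
#' validation cohorts of one synthetic study must share. Pass the result
#' as `template` to [generate_cohort()] for each cohort.
#'
#' @param spec A [cohort_spec()] (its `n_nodes`, `true_edges`,
#'   `coupling_sd`, `effect_size`, `noise_sd` and `seed` fields define
#'   the template).
#' @return List with the base precision matrix, 0-based
#'   `true_edge_indices`, `weights`, and target `signal_scale`.
#' @export
cohort_template <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  m <- spec$n_nodes
  e <- n_edges(m)
  with_seed(spec$seed, {
    b <- matrix(0, m, m)
    b[upper.tri(b)] <- rnorm(e, 0, 0.25 / sqrt(m))
    omega0 <- diag(m) + b + t(b)
    lam <- min(eigen(omega0, symmetric = TRUE, only.values = TRUE)$values)
    if (lam < 0.1) omega0 <- omega0 + diag(0.1 - lam, m)
    true_edges <- sort(sample.int(e, spec$true_edges)) - 1L
    weights <- sample(c(-1, 1), spec$true_edges, replace = TRUE)
    signal_scale <- if (spec$effect_size == 0) 0 else {
      spec$noise_sd * sqrt(spec$effect_size / (1 - spec$effect_size)) /
        (spec$coupling_sd * sqrt(spec$true_edges))
    }
    list(omega0 = omega0, true_edge_indices = true_edges,
         weights = weights, signal_scale = signal_scale,
         n_nodes = m)
  })
}

#' Generate a synthetic cohort
#'
#' Draws a complete cohort under `spec`: per-subject T-by-M Gaussian
#' region timeseries from subject-specific precision matrices (base
#' precision plus perturbed true edges; diagonally re-loaded whenever a
#' perturbation breaks positive definiteness), a behavioral target built
#' from the latent edge strengths, conditioning ratings that embed the
#' target exactly, psychometric and motion covariates, and a confound
#' channel. The exported ground truth reproduces the target to machine
#' precision: `y = intercept + signal_scale * (latent %*% weights) +
#' noise`.
#'
#' @param spec A [cohort_spec()].
#' @param template Optional [cohort_template()] shared across cohorts;
#'   built from `spec` itself when `NULL`.
#' @param seed Seed for subject-level draws (defaults to `spec$seed`).
#' @return Object of class `synthetic_cohort`: `timeseries` (named list
#'   of T-by-M matrices, last column the global gray-matter signal),
#'   `behavior` (valence-rating table; on the raw alternate scale when
#'   `scale_scheme = "vs2"`), `covariates` (motion summaries,
#'   psychometrics, `confound`), and `ground_truth`.
#' @export
generate_cohort <- function(spec, template = NULL, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(template)) template <- cohort_template(spec)
  if (template$n_nodes != spec$n_nodes) {
    abort("template was built for %d nodes, spec has %d",
          template$n_nodes, spec$n_nodes)
  }
  m <- spec$n_nodes
  n <- spec$n_subjects
  k <- spec$true_edges
  tt <- spec$n_timepoints
  pairs <- edge_to_nodes(template$true_edge_indices, m) + 1L # 1-based
  with_seed(seed, {
    latent <- matrix(rnorm(n * k, 0, spec$coupling_sd), n, k)
    node_names <- c(sprintf("region_%03d", seq_len(m - 1)), "global_signal")
    ids <- sprintf("%s_%02d", spec$label, seq_len(n))
    timeseries <- vector("list", n)
    for (s in seq_len(n)) {
      omega <- template$omega0
      for (q in seq_len(k)) {
        i <- pairs[q, 1]; j <- pairs[q, 2]
        omega[i, j] <- omega[i, j] + latent[s, q]
        omega[j, i] <- omega[i, j]
      }
      ch <- NULL
      for (try in 0:40) {
        ch <- tryCatch(chol(omega), error = function(e) NULL)
        if (!is.null(ch)) break
        omega <- omega + diag(0.05, m)
      }
      if (is.null(ch)) abort("could not make subject precision positive definite")
      sigma <- chol2inv(ch)
      ts <- matrix(rnorm(tt * m), tt, m) %*% chol(sigma)
      colnames(ts) <- node_names
      timeseries[[s]] <- ts
    }
    names(timeseries) <- ids

    noise <- rnorm(n, 0, spec$noise_sd)
    signal <- as.numeric(latent %*% template$weights) * template$signal_scale
    y <- spec$intercept + signal + noise

    total_sd <- sqrt(max(var_population(spec, template), .Machine$double.eps))
    z <- (y - spec$intercept) / total_sd
    ce <- spec$confound_effect
    confound <- ce * z + sqrt(max(0, 1 - ce^2)) * rnorm(n)

    tone_dvc <- 15 + 0.6 * (y - spec$intercept) + rnorm(n, 0, 8)
    dvc_table <- data.frame(subject_id = ids, modality = "pain", value = y,
                            stringsAsFactors = FALSE)
    behavior <- build_ratings(ids, y, tone_dvc,
                              scheme = spec$scale_scheme)

    covariates <- data.frame(
      subject_id = ids,
      age = round(pmin(pmax(rnorm(n, 25.3, 3.9), 18), 40), 1),
      depression = round(abs(rnorm(n, 8, 5)), 1),
      fear_pain = runif(n, 20, 80),
      fear_tone = runif(n, 10, 70),
      pain_catastrophizing = round(abs(rnorm(n, 15, 8)), 1),
      pass_d1 = round(abs(rnorm(n, 10, 5)), 1),
      pass_d2 = round(abs(rnorm(n, 10, 5)), 1),
      pass_d3 = round(abs(rnorm(n, 10, 5)), 1),
      pass_d4 = round(abs(rnorm(n, 10, 5)), 1),
      # analyzed-cohort motion regime: cohort sizes represent samples that
      # already passed the registered exclusion, so summaries fall below
      # the limits (the confound channel provides the QC stress test)
      mean_fd = 0.15 * rbeta(n, 2, 4),
      median_fd = 0.12 * rbeta(n, 2, 4),
      max_fd = 0.2 + 0.6 * rbeta(n, 2, 5),
      pct_scrubbed = 25 * rbeta(n, 1.2, 6),
      confound = confound,
      stringsAsFactors = FALSE)

    ground_truth <- list(
      true_edge_indices = template$true_edge_indices,
      latent = latent, weights = template$weights,
      signal_scale = template$signal_scale,
      intercept = spec$intercept, noise = noise, y = y,
      tone_dvc = tone_dvc,
      confound_effect = spec$confound_effect)

    structure(list(label = spec$label, scale_scheme = spec$scale_scheme,
                   timeseries = timeseries, behavior = behavior,
                   covariates = covariates, dvc = dvc_table,
                   ground_truth = ground_truth, spec = spec),
              class = "synthetic_cohort")
  })
}

# population SD^2 of the target under the spec
var_population <- function(spec, template) {
  (template$signal_scale * spec$coupling_sd)^2 * spec$true_edges +
    spec$noise_sd^2
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort '%s': n = %d, M = %d nodes, T = %d, scale = %s\n",
              x$label, x$spec$n_subjects, x$spec$n_nodes,
              x$spec$n_timepoints, x$scale_scheme))
  invisible(x)
}

#' Embed learning scores into conditioning ratings
#'
#' Emits CS+ / CS- valence ratings at habituation and end of acquisition
#' such that [compute_dvc()] recovers each input score to machine
#' precision. The CS- trajectory carries small random jitter; when a
#' score is too large to embed with jittered trajectories inside the
#' rating bounds, the trajectories are shifted as needed, and scores
#' whose magnitude cannot be embedded at all raise an error.
#'
#' @param dvc_scores Numeric vector of differential valence-change
#'   scores, or a data frame with `subject_id` and `value`.
#' @param seed Integer seed.
#' @param modality `"pain"` or `"tone"` (selects the CS+ condition).
#' @return Valence-rating data frame (`subject_id`, `condition`, `phase`,
#'   `value`).
#' @export
generate_ratings_from_dvc <- function(dvc_scores, seed = 1L,
                                      modality = "pain") {
  if (is.data.frame(dvc_scores)) {
    ids <- as.character(dvc_scores$subject_id)
    d <- dvc_scores$value
  } else {
    check_numeric_vector(dvc_scores, "dvc_scores")
    d <- dvc_scores
    ids <- sprintf("s%02d", seq_along(d))
  }
  if (any(!is.finite(d))) abort("DVC scores must be finite")
  with_seed(seed, {
    if (modality == "pain") {
      build_ratings(ids, dvc_pain = d, dvc_tone = NULL, scheme = "default")
    } else {
      build_ratings(ids, dvc_pain = NULL, dvc_tone = d, scheme = "default")
    }
  })
}

# Core embedding. CS- change (shared between modalities) is drawn as
# small jitter, then clamped into the region where every requested CS+
# trajectory fits inside [lo, hi].
build_ratings <- function(ids, dvc_pain = NULL, dvc_tone = NULL,
                          scheme = "default", jitter = 5) {
  lo <- if (scheme == "vs2") 50 else 0
  hi <- 100
  span <- hi - lo
  margin <- 1
  n <- length(ids)
  dmat <- cbind(pain = if (is.null(dvc_pain)) rep(NA, n) else dvc_pain,
                tone = if (is.null(dvc_tone)) rep(NA, n) else dvc_tone)
  rows <- vector("list", n)
  for (s in seq_len(n)) {
    ds <- dmat[s, !is.na(dmat[s, ]), drop = TRUE]
    # CS- change must allow every CS+ change d + delta_minus within span
    feas_lo <- max(-(span - margin) - min(ds, 0), -(span - margin))
    feas_hi <- min((span - margin) - max(ds, 0), span - margin)
    if (feas_lo > feas_hi) {
      abort("subject '%s': DVC magnitude %.1f cannot be embedded in [%g, %g]",
            ids[s], max(abs(ds)), lo, hi)
    }
    pref_lo <- max(feas_lo, -jitter)
    pref_hi <- min(feas_hi, jitter)
    delta_minus <- if (pref_lo <= pref_hi) {
      runif(1, pref_lo, pref_hi)
    } else {
      runif(1, feas_lo, feas_hi)
    }
    hab_minus <- runif(1, max(lo, lo - delta_minus), min(hi, hi - delta_minus))
    out <- data.frame(
      subject_id = ids[s],
      condition = "CS_minus",
      phase = c("habituation", "acquisition_end"),
      value = c(hab_minus, hab_minus + delta_minus),
      stringsAsFactors = FALSE)
    for (mod in names(ds)) {
      delta_plus <- ds[[mod]] + delta_minus
      hab_plus <- runif(1, max(lo, lo - delta_plus), min(hi, hi - delta_plus))
      cond <- if (mod == "pain") "CS_plus_pain" else "CS_plus_tone"
      out <- rbind(out, data.frame(
        subject_id = ids[s], condition = cond,
        phase = c("habituation", "acquisition_end"),
        value = c(hab_plus, hab_plus + delta_plus),
        stringsAsFactors = FALSE))
    }
    rows[[s]] <- out
  }
  ratings <- do.call(rbind, rows)
  if (scheme == "vs2") {
    # store on the raw alternate anchors; harmonize_scale() inverts this
    ratings$value <- (ratings$value - 50) * 2
  }
  rownames(ratings) <- NULL
  ratings
}

#' Behavioral scores of a synthetic cohort via the analysis path
#'
#' Runs a cohort's rating table through the same code path real data
#' take: scale harmonization when the cohort is flagged with the
#' alternate anchors, then [compute_dvc()].
#'
#' @param cohort A `synthetic_cohort`.
#' @param modality `"pain"` or `"tone"`.
#' @return Data frame `subject_id`, `modality`, `value`.
#' @export
score_cohort_behavior <- function(cohort, modality = "pain") {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  ratings <- cohort$behavior
  if (identical(cohort$scale_scheme, "vs2")) {
    ratings$value <- harmonize_scale(ratings$value)
  }
  dvc <- compute_dvc(ratings, modality)
  dvc[match(names(cohort$timeseries), dvc$subject_id), , drop = FALSE]
}

#' Edge matrix of a synthetic cohort
#'
#' Applies the canonical connectome pipeline (standardize, partial
#' correlation, vectorize) to every subject of a cohort.
#'
#' @param cohort A `synthetic_cohort`.
#' @param shrinkage Passed to [partial_correlation()].
#' @return Subjects-by-edges matrix with `n_nodes` and
#'   `ordering_version` attributes.
#' @export
cohort_edge_matrix <- function(cohort, shrinkage = "auto") {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  edge_matrix(cohort$timeseries, shrinkage = shrinkage)
}

#' Synthetic replica of the three-cohort study design
#'
#' Packages the full study scenario: a discovery cohort (n = 25, T =
#' 260), external validation cohort 1 (n = 26, T = 260), and external
#' validation cohort 2 (n = 23, T = 192, ratings stored on the alternate
#' anchor scheme so that [harmonize_scale()] is exercised end to end).
#' All three cohorts are drawn at M = 123 nodes (122 regions plus the
#' global gray-matter signal) from one shared generative template, so a
#' model discovered on the first cohort is validly applicable to the
#' other two.
#'
#' @param seed Integer seed controlling the template and all cohorts.
#' @param n_nodes Node count (123 at study scale; reduce for quick
#'   experiments).
#' @param effect_size,true_edges,coupling_sd Generative signal settings
#'   shared by the three cohorts.
#' @return List with `discovery`, `validation1`, `validation2`
#'   (`synthetic_cohort` objects) and the shared `template`.
#' @export
make_study_replica <- function(seed = 1L, n_nodes = 123, effect_size = 0.5,
                               true_edges = 5, coupling_sd = 0.25) {
  base <- cohort_spec(n_subjects = 25, n_nodes = n_nodes, n_timepoints = 260,
                      true_edges = true_edges, coupling_sd = coupling_sd,
                      effect_size = effect_size, seed = seed,
                      label = "discovery")
  template <- cohort_template(base)
  v1_spec <- cohort_spec(n_subjects = 26, n_nodes = n_nodes,
                         n_timepoints = 260, true_edges = true_edges,
                         coupling_sd = coupling_sd,
                         effect_size = effect_size, seed = seed + 1L,
                         label = "validation1")
  v2_spec <- cohort_spec(n_subjects = 23, n_nodes = n_nodes,
                         n_timepoints = 192, true_edges = true_edges,
                         coupling_sd = coupling_sd,
                         effect_size = effect_size, seed = seed + 2L,
                         label = "validation2", scale_scheme = "vs2")
  list(discovery = generate_cohort(base, template),
       validation1 = generate_cohort(v1_spec, template),
       validation2 = generate_cohort(v2_spec, template),
       template = template)
}
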