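#' Exclusion-loss predictive importance (LOFO / LORO)
#'
#' Quantifies how much a single edge ([lofo()]) or all edges incident to
#' a region ([loro()]) contribute to *externally validated* performance:
#' the candidate feature is removed from the discovery feature space, the
#' complete discovery procedure (univariate selection and nested
#' hyperparameter optimization) is rerun on the reduced space, the
#' truncated frozen model is applied to the external cohort, and the
#' exclusion loss is the drop in external explained variance (squared
#' Pearson correlation), in percentage points. Losses can be negative: a
#' truncated model may generalize better. An edge that the deterministic
#' pipeline never selects and whose removal cannot alter any ranking has
#' a loss of exactly 0.
#'
#' @param X_discovery,y_discovery Discovery edge matrix and target.
#' @param X_validation,y_validation External-validation edge matrix and
#'   target (pooled across external cohorts by convention).
#' @param edge_index Integer vector of 0-based edge indices to exclude,
#'   one model retraining per index.
#' @param grid Hyperparameter grid (see [default_grid()]).
#' @param full_r2 Externally validated squared correlation of the full
#'   model, if already computed; otherwise the full model is (re)fitted
#'   internally with the same grid.
#' @param atlas Optional atlas data frame (see [load_atlas()]) used to
#'   build human-readable labels.
#' @param refit_hyperparameters Rerun the inner hyperparameter search on
#'   the reduced space (default, the full rediscovery). `FALSE` keeps the
#'   full model's `(k, alpha)` fixed: an exploratory fast mode whose
#'   losses are not the registered importance measure.
#' @return Data frame of importance records: `unit_kind`, `unit_id`,
#'   `label`, `exclusion_loss` (percentage points), `r2_full_pct`,
#'   `r2_truncated_pct`, `k`, `alpha`.
#' @export
lofo <- function(X_discovery, y_discovery, X_validation, y_validation,
                 edge_index, grid = default_grid(), full_r2 = NULL,
                 atlas = NULL, refit_hyperparameters = TRUE) {
  ctx <- importance_context(X_discovery, y_discovery, X_validation,
                            y_validation, grid, full_r2,
                            refit_hyperparameters)
  emax <- ncol(X_discovery)
  if (any(edge_index < 0 | edge_index >= emax)) {
    abort("edge index out of range [0, %d)", emax)
  }
  m <- attr(X_discovery, "n_nodes")
  if (is.null(m)) m <- tryCatch(nodes_from_edges(emax), error = function(e) NA)
  rows <- lapply(edge_index, function(e) {
    rec <- truncated_record(ctx, drop_cols = e + 1L)
    lab <- if (!is.na(m)) {
      nodes <- edge_to_nodes(e, m)
      paste(node_labels(nodes[1, ], atlas), collapse = " - ")
    } else {
      sprintf("edge_%d", e)
    }
    cbind(data.frame(unit_kind = "edge", unit_id = e, label = lab,
                     stringsAsFactors = FALSE), rec)
  })
  do.call(rbind, rows)
}

#' @rdname lofo
#' @param region_index Integer vector of 0-based node indices; for each,
#'   all `M - 1` incident edges are excluded. Excluding the global-signal
#'   node is allowed and flagged in the label.
#' @export
loro <- function(X_discovery, y_discovery, X_validation, y_validation,
                 region_index, grid = default_grid(), full_r2 = NULL,
                 atlas = NULL, refit_hyperparameters = TRUE) {
  ctx <- importance_context(X_discovery, y_discovery, X_validation,
                            y_validation, grid, full_r2,
                            refit_hyperparameters)
  m <- attr(X_discovery, "n_nodes")
  if (is.null(m)) m <- nodes_from_edges(ncol(X_discovery))
  if (any(region_index < 0 | region_index >= m)) {
    abort("region index out of range [0, %d)", m)
  }
  pairs <- edge_to_nodes(seq_len(ncol(X_discovery)) - 1L, m)
  rows <- lapply(region_index, function(rg) {
    incident <- which(pairs[, 1] == rg | pairs[, 2] == rg)
    rec <- truncated_record(ctx, drop_cols = incident)
    lab <- node_labels(rg, atlas)
    if (rg == m - 1L) lab <- paste(lab, "(global signal)")
    cbind(data.frame(unit_kind = "region", unit_id = rg, label = lab,
                     stringsAsFactors = FALSE), rec)
  })
  do.call(rbind, rows)
}

# shared setup: validate inputs and fit/score the full model once
importance_context <- function(Xd, yd, Xv, yv, grid, full_r2, refit) {
  stopifnot(is.matrix(Xd), is.matrix(Xv), ncol(Xd) == ncol(Xv))
  fixed_k <- fixed_alpha <- NA
  if (is.null(full_r2) || !refit) {
    full_fit <- nested_cv_discover(Xd, yd, grid = grid)
    if (is.null(full_r2)) full_r2 <- external_r2(full_fit$model, Xv, yv)
    fixed_k <- full_fit$model$k
    fixed_alpha <- full_fit$model$alpha
  }
  list(Xd = Xd, yd = yd, Xv = Xv, yv = yv, grid = grid,
       full_r2 = full_r2, refit = refit,
       fixed_k = fixed_k, fixed_alpha = fixed_alpha)
}

external_r2 <- function(model, Xv, yv) {
  pred <- predict(model, strip_edge_attrs(Xv))
  if (sd(pred) == 0) return(0)
  cor(pred, yv)^2
}

# drop ordering attributes before predicting on a column-subset matrix
strip_edge_attrs <- function(X) {
  attr(X, "n_nodes") <- NULL
  attr(X, "ordering_version") <- NULL
  X
}

truncated_record <- function(ctx, drop_cols) {
  Xd <- strip_edge_attrs(ctx$Xd)[, -drop_cols, drop = FALSE]
  Xv <- strip_edge_attrs(ctx$Xv)[, -drop_cols, drop = FALSE]
  grid <- ctx$grid
  if (!ctx$refit) {
    grid <- list(k = ctx$fixed_k, alpha = ctx$fixed_alpha)
  }
  fit <- nested_cv_discover(Xd, ctx$yd, grid = grid)
  r2_trunc <- external_r2(fit$model, Xv, ctx$yv)
  data.frame(exclusion_loss = 100 * (ctx$full_r2 - r2_trunc),
             r2_full_pct = 100 * ctx$full_r2,
             r2_truncated_pct = 100 * r2_trunc,
             k = fit$model$k, alpha = fit$model$alpha)
}

#' Sort and flag an importance report
#'
#' Sorts importance records by descending exclusion loss and flags those
#' exceeding the significance threshold. Records mixing edge- and
#' region-level units are separated into one table per unit kind.
#'
#' @param records Data frame from [lofo()] / [loro()] (rows may be
#'   concatenated).
#' @param threshold Exclusion-loss significance threshold in percentage
#'   points (default 5.8, the published operating point for single
#'   connections; alternatively derive a cohort-specific null from random
#'   non-model edges).
#' @return A sorted data frame with a `significant` column, or a named
#'   list of two such data frames when both unit kinds are present.
#' @export
importance_table <- function(records, threshold = 5.8) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("'records' must be a non-empty data frame of importance records")
  }
  kinds <- unique(records$unit_kind)
  if (length(kinds) > 1) {
    out <- lapply(split(records, records$unit_kind), importance_table,
                  threshold = threshold)
    return(out)
  }
  records <- records[order(-records$exclusion_loss), , drop = FALSE]
  records$significant <- records$exclusion_loss > threshold
  rownames(records) <- NULL
  records
}
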