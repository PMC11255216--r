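#' Frozen predictive models
#'
#' A frozen model is the fully specified, serializable form of a
#' discovered predictor: selected edge indices (0-based, under the
#' canonical edge ordering), ridge weights, intercept, the chosen
#' hyperparameters, and the per-edge standardization constants learned on
#' the discovery sample. Applying a frozen model involves no fitting of
#' any kind.
#'
#' @param selected_edges Integer vector of 0-based edge indices.
#' @param weights Numeric weights, one per selected edge.
#' @param intercept Numeric intercept (mean of the discovery target).
#' @param k,alpha Hyperparameters the model was fitted with.
#' @param center,scale Standardization constants for the selected edges,
#'   learned on the discovery sample.
#' @param n_nodes Number of connectome nodes the edge ordering refers to.
#' @param target_name Label of the predicted quantity.
#' @param ordering_version Edge-ordering tag (see [EDGE_ORDERING_VERSION]).
#' @return Object of class `frozen_model`.
#' @export
new_frozen_model <- function(selected_edges, weights, intercept, k, alpha,
                             center, scale, n_nodes,
                             target_name = "dvc",
                             ordering_version = EDGE_ORDERING_VERSION) {
  m <- list(selected_edges = as.integer(selected_edges),
            weights = as.numeric(weights),
            intercept = as.numeric(intercept),
            k = as.integer(k), alpha = as.numeric(alpha),
            center = as.numeric(center), scale = as.numeric(scale),
            n_nodes = as.integer(n_nodes),
            target_name = as.character(target_name),
            ordering_version = as.character(ordering_version))
  validate_frozen_model(m)
  class(m) <- "frozen_model"
  m
}

validate_frozen_model <- function(m) {
  k <- length(m$selected_edges)
  if (length(m$weights) != k || m$k != k) {
    abort("frozen model is inconsistent: k = %d but %d edges / %d weights",
          m$k, k, length(m$weights))
  }
  if (length(m$center) != k || length(m$scale) != k) {
    abort("frozen model standardization constants do not match k")
  }
  if (anyNA(unlist(m[c("weights", "intercept", "center", "scale")]))) {
    abort("frozen model contains missing values")
  }
  if (m$alpha < 0) abort("frozen model alpha must be >= 0")
  if (!is.na(m$n_nodes)) {
    emax <- n_edges(m$n_nodes)
    if (any(m$selected_edges < 0 | m$selected_edges >= emax)) {
      abort("selected edge index out of range for %d nodes", m$n_nodes)
    }
  }
  invisible(m)
}

#' @export
print.frozen_model <- function(x, ...) {
  cat(sprintf("Frozen model (%s): %d edges, alpha = %g, intercept = %.3f\n",
              x$target_name, x$k, x$alpha, x$intercept))
  cat(sprintf("  nodes: %s | ordering: %s\n",
              ifelse(is.na(x$n_nodes), "?", x$n_nodes), x$ordering_version))
  invisible(x)
}

#' Serialize a frozen model to JSON (and load it back)
#'
#' Numbers are written at full precision, so a freeze/load round trip
#' reproduces predictions bit-exactly. The file records the edge-ordering
#' tag and node count; loading validates internal consistency (edge count
#' vs. `k`, index ranges) and refuses silently reindexed or truncated
#' files.
#'
#' @param model A `frozen_model`.
#' @param path Output (input) file path.
#' @return `freeze_model` returns `path` invisibly; `load_model` returns
#'   the `frozen_model`.
#' @export
freeze_model <- function(model, path) {
  stopifnot(inherits(model, "frozen_model"))
  validate_frozen_model(model)
  payload <- unclass(model)
  payload$format <- "paincpm-frozen-model/1"
  payload$created <- list(package = "paincpm",
                          version = as.character(packageVersion("paincpm")),
                          date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname freeze_model
#' @export
load_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  # a model without a node count serializes its NA as the string "NA"
  if (is.null(raw$n_nodes) || identical(raw$n_nodes, "NA")) {
    raw$n_nodes <- NA_integer_
  }
  if (!identical(raw$format, "paincpm-frozen-model/1")) {
    abort("'%s' is not a frozen-model file", path)
  }
  if (!identical(raw$ordering_version, EDGE_ORDERING_VERSION)) {
    abort("edge-ordering mismatch: file uses '%s', this package '%s'",
          raw$ordering_version, EDGE_ORDERING_VERSION)
  }
  new_frozen_model(selected_edges = raw$selected_edges,
                   weights = raw$weights, intercept = raw$intercept,
                   k = raw$k, alpha = raw$alpha,
                   center = raw$center, scale = raw$scale,
                   n_nodes = raw$n_nodes, target_name = raw$target_name,
                   ordering_version = raw$ordering_version)
}

#' Apply a frozen model to edge vectors
#'
#' Computes `intercept + sum(weights * standardized(edges))` for each
#' subject using the model's stored standardization constants. No
#' parameter is updated: this is the external-validation path. Edge
#' matrices carrying an `ordering_version` or `n_nodes` attribute that
#' disagrees with the model's are refused outright.
#'
#' @param object A `frozen_model`.
#' @param newdata Numeric edge matrix (subjects x edges) or a single edge
#'   vector.
#' @param ... Unused.
#' @return Named numeric vector of predictions (rating-scale units).
#' @export
predict.frozen_model <- function(object, newdata, ...) {
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1)
  }
  stopifnot(is.matrix(newdata))
  ov <- attr(newdata, "ordering_version")
  if (!is.null(ov) && !identical(ov, object$ordering_version)) {
    abort("edge-ordering mismatch: data '%s' vs model '%s'",
          ov, object$ordering_version)
  }
  nn <- attr(newdata, "n_nodes")
  if (!is.null(nn) && !is.na(object$n_nodes) && nn != object$n_nodes) {
    abort("node-count mismatch: data has %d nodes, model expects %d",
          nn, object$n_nodes)
  }
  if (!is.na(object$n_nodes) && ncol(newdata) != n_edges(object$n_nodes)) {
    abort("edge vector length %d does not match %d nodes (%d edges)",
          ncol(newdata), object$n_nodes, n_edges(object$n_nodes))
  }
  if (anyNA(newdata)) abort("edge data contain missing values")
  z <- sweep(sweep(newdata[, object$selected_edges + 1L, drop = FALSE],
                   2, object$center), 2, object$scale, "/")
  pred <- drop(z %*% object$weights) + object$intercept
  if (!is.null(rownames(newdata))) names(pred) <- rownames(newdata)
  pred
}
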