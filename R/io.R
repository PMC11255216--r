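#' Read and write timeseries cohorts as delimited text
#'
#' The on-disk layout mirrors what preprocessed resting-state data look
#' like in practice: one tab-delimited T-by-M table per subject (header
#' row = node labels, last column the global gray-matter signal) plus a
#' `manifest.tsv` mapping `subject_id` to relative file paths, and
#' tab-delimited behavior/covariate tables.
#'
#' @param cohort A `synthetic_cohort` (or any list with `timeseries`,
#'   `behavior`, `covariates` components).
#' @param dir Output directory (created if needed).
#' @return `write_cohort` returns `dir` invisibly;
#'   `read_timeseries_manifest` returns a named list of numeric
#'   matrices.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(cohort$timeseries)
  paths <- sprintf("%s_timeseries.tsv", ids)
  for (i in seq_along(ids)) {
    write.table(cohort$timeseries[[i]], file.path(dir, paths[i]),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write.table(data.frame(subject_id = ids, path = paths),
              file.path(dir, "manifest.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(cohort$behavior, file.path(dir, "behavior.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(cohort$covariates, file.path(dir, "covariates.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$ground_truth)) {
    jsonlite::write_json(cohort$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @param manifest Path to a `manifest.tsv` with columns `subject_id`
#'   and `path` (relative to the manifest's directory).
#' @export
read_timeseries_manifest <- function(manifest) {
  man <- read.delim(manifest, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "path") %in% names(man))) {
    abort("manifest must have columns subject_id, path")
  }
  base <- dirname(manifest)
  out <- lapply(man$path, function(p) {
    as.matrix(read.delim(file.path(base, p), check.names = FALSE))
  })
  names(out) <- man$subject_id
  out
}
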