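#' Load a region-atlas lookup table
#'
#' Reads a tab-delimited atlas table with columns `index` (0-based node
#' index), `label`, `basc_index` (id in the BASC parcellation), `x`, `y`,
#' `z` (center-of-mass MNI coordinates in mm), `network_group`, and
#' `is_global_signal`. With `path = NULL` the packaged 20-region lookup is
#' returned: the regions incident to the published predictive-signature
#' connections, used for labelling importance reports in examples and
#' tests.
#'
#' @param path Path to a tab-delimited atlas file, or `NULL` for the
#'   packaged fixture.
#' @return Data frame of atlas regions.
#' @export
load_atlas <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "basc_signature_regions.tsv",
                        package = "paincpm", mustWork = TRUE)
  }
  at <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  req <- c("index", "label", "basc_index", "x", "y", "z")
  if (!all(req %in% names(at))) {
    abort("atlas file must contain columns %s", paste(req, collapse = ", "))
  }
  if (anyDuplicated(at$index)) abort("atlas node indices must be unique")
  if (!"is_global_signal" %in% names(at)) at$is_global_signal <- FALSE
  at
}

# resolve 0-based node indices to labels; unknown indices fall back to
# "node_<i>"
node_labels <- function(idx, atlas = NULL) {
  if (is.null(atlas)) return(sprintf("node_%d", idx))
  pos <- match(idx, atlas$index)
  out <- atlas$label[pos]
  out[is.na(pos)] <- sprintf("node_%d", idx[is.na(pos)])
  out
}
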