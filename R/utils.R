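# Internal helpers shared across stages.
#
# Event tables are plain tibbles: one row per cell, one column per marker,
# plus dot-prefixed metadata columns (.sample_id, .condition, .group,
# .population, .cluster, .area) that every stage ignores when computing on
# expression values. Transform state travels in the "transform"/"cofactor"
# attributes.

#' Marker columns of an event table
#'
#' Returns the names of the expression columns of an event table, i.e. all
#' columns whose name does not start with a dot. Dot-prefixed columns
#' (`.sample_id`, `.condition`, `.group`, `.population`, `.cluster`,
#' `.area`, ...) carry per-cell metadata and are never treated as markers.
#'
#' @param events A data frame of cells by markers.
#' @return Character vector of marker column names.
#' @export
marker_cols <- function(events) {
  nm <- names(events)
  nm[!startsWith(nm, ".")]
}

#' Extract the expression matrix of an event table
#'
#' @param events A data frame of cells by markers.
#' @param markers Markers to extract; defaults to all marker columns.
#' @return A numeric matrix (cells x markers).
#' @export
event_matrix <- function(events, markers = marker_cols(events)) {
  missing <- setdiff(markers, names(events))
  if (length(missing) > 0) {
    abort(paste0("unknown marker(s): ", paste(missing, collapse = ", ")))
  }
  as.matrix(events[markers])
}

events_transform <- function(events) attr(events, "transform") %||% "raw"

set_events_transform <- function(events, transform, cofactor = NULL) {
  attr(events, "transform") <- transform
  attr(events, "cofactor") <- cofactor
  events
}

# Stable per-purpose seed derivation: small offsets from a base seed keep
# every stage independently reproducible while staying within 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483647L)
}

`%||%` <- rlang::`%||%`
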