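#' Read a single-cell cytometry sample
#'
#' Reads one sample (cells x markers) from an FCS 3.0/3.1 file or from a
#' delimited-text fallback (comma-separated, header row of marker names, one
#' cell per line). Values are returned on the raw scale; apply
#' [asinh_events()] before clustering.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"fcs"`, or `"csv"`.
#' @param panel Optional [marker_panel()]; if supplied, the file must contain
#'   every panel marker (error lists any that are missing) and columns are
#'   reordered to panel order.
#' @param sample_id Sample identifier recorded in the `.sample_id` column;
#'   defaults to the file name without extension.
#' @param condition,group Optional `.condition` / `.group` metadata values.
#' @return A tibble of cells by markers with `transform = "raw"`.
#' @export
read_events <- function(path, format = c("auto", "fcs", "csv"), panel = NULL,
                        sample_id = NULL, condition = NULL, group = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  if (format == "fcs") {
    mat <- read_fcs(path)
    events <- tibble::as_tibble(mat, .name_repair = "minimal")
  } else {
    df <- read.csv(path, check.names = FALSE)
    if (ncol(df) == 0 || nrow(df) == 0) {
      abort("malformed CSV: no cells or no markers",
            class = "cytoforge_format_error")
    }
    names(df) <- trimws(names(df))
    events <- tibble::as_tibble(df)
  }
  if (!is.null(panel)) {
    missing <- setdiff(panel$marker, names(events))
    if (length(missing) > 0) {
      abort(paste0("sample is missing panel marker(s): ",
                   paste(missing, collapse = ", ")),
            class = "cytoforge_panel_error")
    }
    events <- events[panel$marker]
  }
  events$.sample_id <- sample_id %||% sub("\\.[^.]+$", "", basename(path))
  if (!is.null(condition)) events$.condition <- condition
  if (!is.null(group)) events$.group <- group
  set_events_transform(events, "raw")
}

#' Write a single-cell cytometry sample
#'
#' Writes the marker columns of an event table to FCS 3.1 (32-bit float,
#' little-endian list mode) or delimited CSV. Metadata columns (dot-prefixed)
#' are not written; FCS stores marker names in both $PnN and $PnS.
#'
#' @param events Event table with at least one marker column and one cell.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"fcs"`, or `"csv"`.
#' @return The path, invisibly.
#' @export
write_events <- function(events, path, format = c("auto", "fcs", "csv")) {
  format <- match.arg(format)
  markers <- marker_cols(events)
  if (length(markers) == 0) abort("cannot write a sample with no markers")
  if (nrow(events) == 0) abort("cannot write a sample with no cells")
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  mat <- event_matrix(events, markers)
  if (format == "fcs") {
    write_fcs(mat, path)
  } else {
    ok <- tryCatch({
      write.csv(as.data.frame(mat), path, row.names = FALSE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) abort(paste0("cannot write to ", path))
  }
  invisible(path)
}

#' Arcsinh-transform an event table
#'
#' Applies the standard mass-cytometry variance-stabilizing transform
#' `asinh(x / cofactor)` to every marker column. The transform state is
#' recorded so a table cannot be transformed twice.
#'
#' @param events Raw event table.
#' @param cofactor Positive scale cofactor; 5 is the CyTOF convention.
#' @return The transformed table with `transform = "arcsinh"`.
#' @export
asinh_events <- function(events, cofactor = 5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1 || cofactor <= 0) {
    abort("cofactor must be a positive number")
  }
  if (events_transform(events) == "arcsinh") {
    abort("events are already arcsinh-transformed")
  }
  markers <- marker_cols(events)
  events[markers] <- lapply(events[markers], function(x) asinh(x / cofactor))
  set_events_transform(events, "arcsinh", cofactor)
}

#' Concatenate samples into one event table
#'
#' Row-stacks a list of event tables, recording per-cell provenance in the
#' `.sample_id` column. All samples must share one marker set and one
#' transform state.
#'
#' @param samples List of event tables (or a single table).
#' @return One event table with a `.sample_id` provenance column.
#' @export
bind_samples <- function(samples) {
  if (is.data.frame(samples)) samples <- list(samples)
  if (length(samples) == 0) abort("no samples to concatenate")
  ref_markers <- marker_cols(samples[[1]])
  transforms <- vapply(samples, events_transform, character(1))
  if (length(unique(transforms)) != 1) {
    abort("cannot concatenate samples with mixed transform states",
          class = "cytoforge_state_error")
  }
  for (s in samples) {
    if (!setequal(marker_cols(s), ref_markers)) {
      abort("samples do not share one marker panel",
            class = "cytoforge_panel_error")
    }
    if (!".sample_id" %in% names(s)) {
      abort("every sample needs a .sample_id column (set by read_events or the simulator)")
    }
  }
  out <- dplyr::bind_rows(samples)
  set_events_transform(out, transforms[1], attr(samples[[1]], "cofactor"))
}

#' Subsample an equal number of cells from each sample
#'
#' Draws the same number of cells, without replacement, from every sample so
#' that each contributes equally to downstream pooled analyses (embeddings in
#' particular). If any sample has fewer than `n_per_sample` cells the target
#' is clamped to the minimum cell count across samples.
#'
#' @param samples List of event tables.
#' @param n_per_sample Target cells per sample (positive).
#' @param seed Integer seed; the selection is reproducible under a fixed
#'   seed.
#' @return List of event tables, all with the same number of cells.
#' @export
subsample_equal <- function(samples, n_per_sample, seed = 1L) {
  if (is.data.frame(samples)) samples <- list(samples)
  if (!is.numeric(n_per_sample) || n_per_sample <= 0) {
    abort("n_per_sample must be a positive integer")
  }
  n <- min(n_per_sample, min(vapply(samples, nrow, integer(1))))
  out <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    set.seed(derive_seed(seed, i))
    keep <- sort(sample.int(nrow(samples[[i]]), n))
    sub <- samples[[i]][keep, , drop = FALSE]
    out[[i]] <- set_events_transform(sub, events_transform(samples[[i]]),
                                     attr(samples[[i]], "cofactor"))
  }
  names(out) <- names(samples)
  out
}
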