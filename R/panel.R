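#' Construct a marker panel
#'
#' A marker panel records, per marker, the metal tag, the stain class
#' (extracellular or intracellular), and membership of named clustering sets.
#' Clustering sets are the marker subsets the different analysis arms use:
#' the full panel for the main clustering, a 20-marker subset for the
#' stimulation arm, and a 9-marker annotation set for cell-type calls.
#'
#' @param markers Character vector of unique marker names.
#' @param metal_tag Per-marker metal tag labels.
#' @param stain_class Per-marker `"extracellular"` or `"intracellular"`.
#' @param clustering_sets Named list of character vectors, each a subset of
#'   `markers`.
#' @return A tibble with one row per marker and a `clustering_sets`
#'   attribute.
#' @export
marker_panel <- function(markers, metal_tag, stain_class,
                         clustering_sets = list()) {
  if (length(markers) == 0) abort("a panel needs at least one marker")
  markers <- trimws(markers)
  if (anyDuplicated(markers)) abort("marker names must be unique")
  if (length(metal_tag) != length(markers) ||
      length(stain_class) != length(markers)) {
    abort("metal_tag and stain_class must match the number of markers")
  }
  if (!all(stain_class %in% c("extracellular", "intracellular"))) {
    abort("stain_class must be 'extracellular' or 'intracellular'")
  }
  for (nm in names(clustering_sets)) {
    extra <- setdiff(clustering_sets[[nm]], markers)
    if (length(extra) > 0) {
      abort(paste0("clustering set '", nm, "' contains unknown marker(s): ",
                   paste(extra, collapse = ", ")))
    }
  }
  panel <- tibble::tibble(marker = markers, metal_tag = metal_tag,
                          stain_class = stain_class)
  attr(panel, "clustering_sets") <- clustering_sets
  class(panel) <- c("marker_panel", class(panel))
  panel
}

#' Markers of a named clustering set
#'
#' @param panel A [marker_panel()].
#' @param set Name of the clustering set, e.g. `"all33"`, `"stim20"`,
#'   `"annotation9"`.
#' @return Character vector of marker names.
#' @export
clustering_markers <- function(panel, set) {
  sets <- attr(panel, "clustering_sets")
  if (is.null(sets) || !set %in% names(sets)) {
    abort(paste0("unknown clustering set '", set, "'"))
  }
  sets[[set]]
}

#' Read a panel definition file
#'
#' Panel files are CSV with columns `marker`, `metal_tag`, `stain_class`
#' and one logical column per clustering set. The shipped 33-marker panel
#' lives at `system.file("extdata", "panel_33.csv", package = "cytoforge")`.
#'
#' @param path Panel CSV path.
#' @return A [marker_panel()].
#' @export
read_panel <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  fixed <- c("marker", "metal_tag", "stain_class")
  if (!all(fixed %in% names(df))) {
    abort("panel file needs marker, metal_tag and stain_class columns")
  }
  set_cols <- setdiff(names(df), fixed)
  sets <- lapply(set_cols, function(s) df$marker[as.logical(df[[s]])])
  names(sets) <- set_cols
  marker_panel(df$marker, df$metal_tag, df$stain_class, sets)
}

# 20-marker set used by the stimulation-arm clustering.
stim20_markers <- function() {
  c("CD3", "CD11a", "CD11b", "CD11c", "CD14", "CD16", "CD19", "CD23",
    "CD28", "CD32", "CD64", "CD66", "CD86", "CD123", "CCR5", "CXCR4",
    "GranzymeB", "Perforin", "TLR2", "HLADR")
}

#' Default 33-marker leukocyte panel
#'
#' A whole-blood innate/adaptive immunophenotyping panel. Twenty
#' surface/functional markers form the `"stim20"` clustering set, three
#' intracellular cytokines (MIP-1beta, TNF-alpha, IL-8) support stimulation
#' readouts, and ten additional common leukocyte markers complete the panel
#' to 33 channels; the completion markers are synthetic panel filler used by
#' the cohort simulator, not measurements of any particular instrument
#' configuration. The `"annotation9"` set (CD3, CD11c, CD14, CD16, CD19,
#' CD66, CD123, Granzyme B, HLADR) drives cell-type annotation;
#' `"annotation9_stim"` swaps Granzyme B for CD64 for the stimulation arm.
#'
#' @return A [marker_panel()] of 33 markers with clustering sets `all33`,
#'   `stim20`, `annotation9`, `annotation9_stim`, `cytokines`.
#' @export
default_panel <- function() {
  stim <- stim20_markers()
  cytokines <- c("MIP1b", "TNFa", "IL8")
  filler <- c("CD45", "CD15", "CD20", "CD24", "CD36", "CD38",
              "CD56", "CD62L", "CD69", "IL6")
  markers <- c(stim, cytokines, filler)
  tags <- c("In115", "La139", "Pr141", "Nd142", "Nd143", "Nd144", "Nd145",
            "Nd146", "Sm147", "Nd148", "Sm149", "Nd150", "Eu151", "Sm152",
            "Eu153", "Sm154", "Gd155", "Gd156", "Gd158", "Tb159", "Gd160",
            "Dy161", "Dy162", "Dy163", "Dy164", "Ho165", "Er166", "Er167",
            "Er168", "Tm169", "Er170", "Yb171", "Yb172")
  intracellular <- c("GranzymeB", "Perforin", "MIP1b", "TNFa", "IL8", "IL6")
  marker_panel(
    markers,
    metal_tag = tags,
    stain_class = ifelse(markers %in% intracellular,
                         "intracellular", "extracellular"),
    clustering_sets = list(
      all33 = markers,
      stim20 = stim,
      annotation9 = c("CD3", "CD11c", "CD14", "CD16", "CD19", "CD66",
                      "CD123", "GranzymeB", "HLADR"),
      annotation9_stim = c("CD3", "CD11c", "CD14", "CD16", "CD19", "CD66",
                           "CD123", "CD64", "HLADR"),
      cytokines = cytokines
    )
  )
}
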