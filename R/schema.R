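#' Labeling schema: the phase-by-item rating grid
#'
#' A labeling schema defines which movement phases and movement directions
#' (items) make up one video's rating sheet. The default schema mirrors the
#' drinking-task instrument: 5 phases x 11 movement directions = 55 slider
#' fields per video, two of which (`smoothness`, `interjoint_coordination`)
#' are "global" movement-quality domains that are reported across phases
#' rather than inside phase means.
#'
#' @param phases Character vector of ordered phase identifiers.
#' @param items Character vector of ordered movement-direction identifiers.
#' @param global_items Character vector, subset of `items`, flagged as global
#'   movement-quality domains.
#'
#' @return An object of class `labeling_schema`: a list with elements
#'   `phases`, `items`, `global_items`.
#' @examples
#' sch <- drinking_task_schema()
#' length(sch$phases) * length(sch$items) # 55 fields per video
#' @export
labeling_schema <- function(phases, items, global_items = character()) {
  phases <- as.character(phases)
  items <- as.character(items)
  global_items <- as.character(global_items)
  if (anyDuplicated(phases)) stop("duplicate phase identifiers", call. = FALSE)
  if (anyDuplicated(items)) stop("duplicate item identifiers", call. = FALSE)
  if (!all(global_items %in% items)) {
    stop("global_items must be a subset of items", call. = FALSE)
  }
  structure(
    list(phases = phases, items = items, global_items = global_items),
    class = "labeling_schema"
  )
}

#' @rdname labeling_schema
#' @export
drinking_task_schema <- function() {
  labeling_schema(
    phases = c(
      "reaching", "forward_transport", "drinking",
      "back_transport", "returning"
    ),
    items = c(
      "trunk_lateral_flexion_rotation", "trunk_flexion",
      "shoulder_flexion", "shoulder_horizontal_adduction",
      "elbow_extension", "elbow_flexion",
      "forearm_pronation_supination", "wrist_flexion",
      "grasp_hand_opening", "smoothness", "interjoint_coordination"
    ),
    global_items = c("smoothness", "interjoint_coordination")
  )
}

#' Read a labeling schema from a YAML or JSON config file
#'
#' The file must contain keys `phases` and `items` (lists of strings) and may
#' contain `global_items`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [labeling_schema()].
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML schemas requires the 'yaml' package", call. = FALSE)
    }
    yaml::read_yaml(path)
  }
  if (is.null(cfg$phases) || is.null(cfg$items)) {
    stop("schema config must define 'phases' and 'items'", call. = FALSE)
  }
  labeling_schema(cfg$phases, cfg$items, cfg$global_items %||% character())
}

#' @export
print.labeling_schema <- function(x, ...) {
  cat("<labeling_schema>\n")
  cat("  phases (", length(x$phases), "): ",
    paste(x$phases, collapse = ", "), "\n",
    sep = ""
  )
  cat("  items  (", length(x$items), "): ",
    paste(x$items, collapse = ", "), "\n",
    sep = ""
  )
  cat("  global: ", paste(x$global_items, collapse = ", "), "\n", sep = "")
  cat("  fields per video: ", length(x$phases) * length(x$items), "\n",
    sep = ""
  )
  invisible(x)
}

#' Non-global items of a schema
#'
#' @param schema A [labeling_schema()].
#' @return Character vector of items that enter phase means.
#' @export
phase_items <- function(schema) {
  setdiff(schema$items, schema$global_items)
}
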