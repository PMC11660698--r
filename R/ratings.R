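#' Read and validate a long-format rating table
#'
#' Ratings are stored one row per (rater, video, phase, item, round) with
#' either a slider value in \[0, 100\] or a not-assessable flag. In CSV the
#' not-assessable state is encoded by the literal token
#' `"NA_not_assessable"` in the `value` column (or `TRUE` in an optional
#' `not_assessable` column); an absent row means the cell was never rated,
#' which is distinct from not-assessable.
#'
#' @param path Path to a CSV file (UTF-8, header row) with columns
#'   `rater_id`, `video_id`, `phase`, `item`, `round`, `value` and optionally
#'   `not_assessable`.
#' @param schema A [labeling_schema()] used to validate phases and items.
#' @return A tibble of validated rating records with columns `rater_id`,
#'   `video_id`, `phase`, `item` (character), `round` (integer), `value`
#'   (double, `NA` when not assessable) and `not_assessable` (logical).
#' @seealso [write_ratings()], [validate_ratings()]
#' @export
read_ratings <- function(path, schema = drinking_task_schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  needed <- c("rater_id", "video_id", "phase", "item", "round", "value")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop(
      "missing required column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(raw) == 0) stop("no records in ", path, call. = FALSE)

  na_token <- raw$value == "NA_not_assessable"
  na_token[is.na(na_token)] <- FALSE
  flag_col <- if ("not_assessable" %in% names(raw)) {
    toupper(trimws(raw$not_assessable)) %in% c("TRUE", "T", "1")
  } else {
    rep(FALSE, nrow(raw))
  }
  not_assessable <- na_token | flag_col

  value <- suppressWarnings(as.numeric(raw$value))
  value[not_assessable] <- NA_real_
  bad_parse <- which(!not_assessable & is.na(value))
  if (length(bad_parse) > 0) {
    stop(
      "row ", bad_parse[1], ": value ", encodeString(raw$value[bad_parse[1]]),
      " is neither a number nor the not-assessable token",
      call. = FALSE
    )
  }

  out <- tibble::tibble(
    rater_id = as.character(raw$rater_id),
    video_id = as.character(raw$video_id),
    phase = as.character(raw$phase),
    item = as.character(raw$item),
    round = as.integer(raw$round),
    value = value,
    not_assessable = not_assessable
  )
  validate_ratings(out, schema)
}

#' Validate a rating table against its schema and invariants
#'
#' Checks: required columns, value range \[0, 100\], exactly one of
#' value / not-assessable per row, known phases and items, no duplicate
#' (rater, video, phase, item, round) keys. Errors name the first offending
#' row and field.
#'
#' @param data A rating tibble as returned by [read_ratings()] or
#'   [simulate_ratings()].
#' @inheritParams read_ratings
#' @return `data`, invisibly unchanged, as a tibble.
#' @export
validate_ratings <- function(data, schema = drinking_task_schema()) {
  data <- tibble::as_tibble(data)
  needed <- c(
    "rater_id", "video_id", "phase", "item", "round",
    "value", "not_assessable"
  )
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop(
      "missing required column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(data) == 0) stop("no records", call. = FALSE)

  bad <- which(is.na(data$value) & !data$not_assessable)
  if (length(bad) > 0) {
    stop("row ", bad[1], ": value absent but not flagged not-assessable",
      call. = FALSE
    )
  }
  bad <- which(!is.na(data$value) & data$not_assessable)
  if (length(bad) > 0) {
    stop("row ", bad[1], ": both value and not-assessable set", call. = FALSE)
  }
  bad <- which(!is.na(data$value) & (data$value < 0 | data$value > 100))
  if (length(bad) > 0) {
    stop("row ", bad[1], ": value ", data$value[bad[1]],
      " outside [0, 100]",
      call. = FALSE
    )
  }
  bad <- which(!data$phase %in% schema$phases)
  if (length(bad) > 0) {
    stop("row ", bad[1], ": unknown phase ", encodeString(data$phase[bad[1]]),
      call. = FALSE
    )
  }
  bad <- which(!data$item %in% schema$items)
  if (length(bad) > 0) {
    stop("row ", bad[1], ": unknown item ", encodeString(data$item[bad[1]]),
      call. = FALSE
    )
  }
  if (!all(data$round %in% c(1L, 2L))) {
    bad <- which(!data$round %in% c(1L, 2L))
    stop("row ", bad[1], ": round must be 1 or 2", call. = FALSE)
  }
  key <- paste(data$rater_id, data$video_id, data$phase, data$item,
    data$round,
    sep = "\r"
  )
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("row ", dup[1], ": duplicate (rater, video, phase, item, round) key",
      call. = FALSE
    )
  }
  data
}

#' Write a rating table to CSV
#'
#' Inverse of [read_ratings()]: not-assessable rows are written with the
#' `"NA_not_assessable"` token in the `value` column so the file round-trips.
#'
#' @inheritParams validate_ratings
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(data, path) {
  out <- dplyr::mutate(
    data,
    value = ifelse(.data$not_assessable, "NA_not_assessable",
      format(.data$value, trim = TRUE, digits = 15)
    )
  )
  readr::write_csv(
    dplyr::select(
      out, "rater_id", "video_id", "phase", "item", "round",
      "value", "not_assessable"
    ),
    path, progress = FALSE
  )
  invisible(path)
}

#' Convert between long and wide (one column per field) rating layouts
#'
#' The wide layout mirrors a data-capture export: one row per
#' (rater, video, round) and one `phase.item` column per schema field.
#'
#' @inheritParams validate_ratings
#' @return For `ratings_to_wide()`, a tibble with one row per
#'   (rater, video, round); for `ratings_to_long()`, the canonical long
#'   tibble.
#' @export
ratings_to_wide <- function(data, schema = drinking_task_schema()) {
  data |>
    dplyr::mutate(
      field = paste(.data$phase, .data$item, sep = "."),
      cell = ifelse(.data$not_assessable, "NA_not_assessable",
        format(.data$value, trim = TRUE, digits = 15)
      )
    ) |>
    dplyr::select("rater_id", "video_id", "round", "field", "cell") |>
    tidyr::pivot_wider(names_from = "field", values_from = "cell")
}

#' @rdname ratings_to_wide
#' @param wide A tibble produced by [ratings_to_wide()].
#' @export
ratings_to_long <- function(wide, schema = drinking_task_schema()) {
  long <- wide |>
    tidyr::pivot_longer(
      cols = -c("rater_id", "video_id", "round"),
      names_to = "field", values_to = "cell"
    ) |>
    dplyr::filter(!is.na(.data$cell)) |>
    tidyr::separate_wider_delim("field",
      delim = ".",
      names = c("phase", "item"), too_many = "merge"
    )
  long |>
    dplyr::mutate(
      not_assessable = .data$cell == "NA_not_assessable",
      value = ifelse(.data$not_assessable, NA_real_,
        suppressWarnings(as.numeric(.data$cell))
      ),
      round = as.integer(.data$round)
    ) |>
    dplyr::select(
      "rater_id", "video_id", "phase", "item", "round",
      "value", "not_assessable"
    ) |>
    validate_ratings(schema)
}

#' Drop both rounds of any cell flagged not-assessable in either round
#'
#' For every (rater, video, phase, item) cell in which round 1, round 2, or
#' both carry the not-assessable flag, all of that cell's records are
#' removed; every other record is retained unchanged. The operation is
#' idempotent and an empty result is legal.
#'
#' @inheritParams validate_ratings
#' @return The filtered rating tibble.
#' @export
exclude_not_assessable <- function(data) {
  flagged <- data |>
    dplyr::filter(.data$not_assessable) |>
    dplyr::distinct(.data$rater_id, .data$video_id, .data$phase, .data$item)
  dplyr::anti_join(
    data, flagged,
    by = c("rater_id", "video_id", "phase", "item")
  )
}

#' Phase-level mean scores per rater, video and round
#'
#' Averages the available item values within each (rater, video, phase,
#' round) cell. By default the two global movement-quality domains
#' (smoothness, interjoint coordination) are left out of phase means: they
#' are analysed as overall domains across phases and would double-count
#' otherwise. Cells with no available items (all excluded) are dropped.
#'
#' @inheritParams validate_ratings
#' @param include_global Logical; include the schema's global items in the
#'   phase means?
#' @return A tibble with columns `rater_id`, `video_id`, `phase`, `round`,
#'   `score` (mean on the 0-100 scale) and `n_items`.
#' @export
aggregate_phase_scores <- function(data, schema = drinking_task_schema(),
                                   include_global = FALSE) {
  keep <- if (include_global) schema$items else phase_items(schema)
  data |>
    dplyr::filter(!.data$not_assessable, .data$item %in% keep) |>
    dplyr::summarise(
      score = mean(.data$value),
      n_items = dplyr::n(),
      .by = c("rater_id", "video_id", "phase", "round")
    )
}

#' Overall score for one global domain, averaged across phases
#'
#' Collapses a global item (e.g. smoothness) over all phases to one score
#' per (rater, video, round), the shape expected by the reliability
#' pipeline for the overall smoothness / interjoint-coordination domains.
#'
#' @inheritParams validate_ratings
#' @param item One of `schema$global_items`.
#' @return A tibble with columns `rater_id`, `video_id`, `phase` (set to the
#'   item name so the table is drop-in compatible with phase-level tables),
#'   `round`, `score`, `n_items`.
#' @export
aggregate_global_scores <- function(data, item,
                                    schema = drinking_task_schema()) {
  if (!item %in% schema$global_items) {
    stop(encodeString(item), " is not a global item of the schema",
      call. = FALSE
    )
  }
  data |>
    dplyr::filter(!.data$not_assessable, .data$item == !!item) |>
    dplyr::summarise(
      score = mean(.data$value),
      n_items = dplyr::n(),
      .by = c("rater_id", "video_id", "round")
    ) |>
    dplyr::mutate(phase = !!item) |>
    dplyr::select(
      "rater_id", "video_id", "phase", "round", "score", "n_items"
    )
}

#' Summarise the dimensions of a rating dataset
#'
#' @inheritParams validate_ratings
#' @return A one-row tibble: numbers of raters, videos, rounds, fields per
#'   (rater, video, round) (maximum observed), and total records.
#' @export
dataset_dimensions <- function(data) {
  per_sheet <- dplyr::count(
    data, .data$rater_id, .data$video_id, .data$round
  )
  tibble::tibble(
    n_raters = dplyr::n_distinct(data$rater_id),
    n_videos = dplyr::n_distinct(data$video_id),
    n_rounds = dplyr::n_distinct(data$round),
    fields_per_sheet = max(per_sheet$n),
    n_records = nrow(data)
  )
}
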