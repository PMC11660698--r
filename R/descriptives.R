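#' Zero-concordance between labeling rounds
#'
#' For each phase, counts the (rater, video, item) pairs rated in both
#' rounds and how many of them are exact zeros in both - the "no
#' compensation in either round" agreement that dominates scatterplots of
#' round 1 against round 2 for mildly affected videos.
#'
#' @param data A rating tibble with both rounds (exclusion applied).
#' @return A tibble per phase: `n_pairs`, `n_both_zero`.
#' @export
zero_concordance <- function(data) {
  paired_rounds(data) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      n_both_zero = sum(.data$value_1 == 0 & .data$value_2 == 0),
      .by = "phase"
    )
}

#' Round-to-round deviation summary
#'
#' Characteristic values of the paired differences (round 1 minus round 2,
#' slider units) per phase.
#'
#' @inheritParams zero_concordance
#' @return A tibble per phase: `n_pairs`, `mean_diff`, `sd_diff`,
#'   `min_diff`, `max_diff`.
#' @export
round_deviation_summary <- function(data) {
  paired_rounds(data) |>
    dplyr::mutate(diff = .data$value_1 - .data$value_2) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      mean_diff = mean(.data$diff),
      sd_diff = stats::sd(.data$diff),
      min_diff = min(.data$diff),
      max_diff = max(.data$diff),
      .by = "phase"
    )
}

# one row per (rater, video, phase, item) with value_1 / value_2 columns
paired_rounds <- function(data) {
  data |>
    dplyr::filter(!.data$not_assessable, .data$round %in% c(1L, 2L)) |>
    dplyr::select(
      "rater_id", "video_id", "phase", "item", "round", "value"
    ) |>
    tidyr::pivot_wider(
      names_from = "round", values_from = "value", names_prefix = "value_"
    ) |>
    dplyr::filter(!is.na(.data$value_1), !is.na(.data$value_2))
}

#' Tally not-assessable flags
#'
#' Counts flags per round and per (phase, item, round) on the raw
#' (pre-exclusion) dataset.
#'
#' @param data A raw rating tibble.
#' @return A list with `by_round` (tibble: `round`, `n_flags`) and
#'   `by_field` (tibble: `phase`, `item`, `round`, `n_flags`).
#' @export
not_assessable_tally <- function(data) {
  rounds <- sort(unique(data$round))
  by_round <- data |>
    dplyr::summarise(
      n_flags = sum(.data$not_assessable), .by = "round"
    ) |>
    dplyr::arrange(.data$round)
  by_field <- data |>
    dplyr::filter(.data$not_assessable) |>
    dplyr::count(.data$phase, .data$item, .data$round, name = "n_flags") |>
    dplyr::arrange(dplyr::desc(.data$n_flags))
  list(by_round = by_round, by_field = by_field)
}

#' Naive ANOVA-based ICC (didactic comparison only)
#'
#' Two-way mean-squares ICC for absolute agreement with single raters
#' (ICC(2,1)) computed from a (video x rater) score table for one round.
#' This is *not* the package's reliability method: it assumes normal,
#' homoscedastic scores, which zero-inflated bounded ratings violate. It
#' is provided so the distortion under zero inflation can be demonstrated
#' against the mixed-model ICC.
#'
#' @param scores A tibble with columns `video_id`, `rater_id`, `score`
#'   (one round; one score per video-rater pair).
#' @return A scalar ICC(2,1) estimate.
#' @export
icc_anova <- function(scores) {
  stopifnot(all(c("video_id", "rater_id", "score") %in% names(scores)))
  wide <- scores |>
    dplyr::select("video_id", "rater_id", "score") |>
    tidyr::pivot_wider(names_from = "rater_id", values_from = "score") |>
    dplyr::select(-"video_id") |>
    as.matrix()
  if (anyNA(wide)) stop("unbalanced table: every rater must score every video",
      call. = FALSE
    )
  n <- nrow(wide)
  k <- ncol(wide)
  grand <- mean(wide)
  msr <- k * sum((rowMeans(wide) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(wide) - grand)^2) / (k - 1)
  sst <- sum((wide - grand)^2)
  mse <- (sst - (n - 1) * msr - (k - 1) * msc) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}
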