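#' Intraclass correlations from posterior variance components
#'
#' Computes the inter- or intra-rater ICC draw by draw on the latent
#' (logit) scale and summarises the posterior:
#' \itemize{
#'   \item inter: `sigma2_video / (sigma2_video + sigma2_rater +
#'     sigma2_rater_video + sigma2_round)` - the correlation between two
#'     different raters' latent scores of the same video;
#'   \item intra: `(sigma2_video + sigma2_rater + sigma2_rater_video) /
#'     (same denominator)` - the test-retest correlation of one rater on
#'     one video, so every cell-stable component enters the numerator.
#' }
#' The point estimate is the posterior median and the interval the
#' equal-tailed 2.5%/97.5% quantiles. Draws with an all-zero denominator
#' are excluded (with their count reported); more than 10% exclusions is
#' an error.
#'
#' @param draws A `zib_fit` or its `draws` tibble (columns `sigma2_video`,
#'   `sigma2_rater`, `sigma2_rater_video`, `sigma2_round`).
#' @param target `"inter"` or `"intra"`.
#' @param scope Optional label (phase or global domain) carried into the
#'   result; defaults to the fit's scope when available.
#' @param conf_level Credible-interval mass (default 0.95).
#' @return A one-row tibble: `target`, `scope`, `point`, `ci_low`,
#'   `ci_high`, `n_draws`, `n_excluded`.
#' @export
icc_from_draws <- function(draws, target = c("inter", "intra"),
                           scope = NULL, conf_level = 0.95) {
  target <- match.arg(target)
  if (inherits(draws, "zib_fit")) {
    scope <- scope %||% draws$scope
    draws <- draws$draws
  }
  scope <- scope %||% NA_character_
  need <- c(
    "sigma2_video", "sigma2_rater", "sigma2_rater_video", "sigma2_round"
  )
  stopifnot(all(need %in% names(draws)))
  if (any(unlist(draws[need]) < 0)) {
    stop("negative variance draws", call. = FALSE)
  }
  denom <- draws$sigma2_video + draws$sigma2_rater +
    draws$sigma2_rater_video + draws$sigma2_round
  bad <- denom == 0
  n_excluded <- sum(bad)
  if (n_excluded > 0.1 * length(denom)) {
    stop(
      n_excluded, " of ", length(denom),
      " draws have an all-zero denominator (> 10%)",
      call. = FALSE
    )
  }
  num <- if (target == "inter") {
    draws$sigma2_video
  } else {
    draws$sigma2_video + draws$sigma2_rater + draws$sigma2_rater_video
  }
  icc <- (num / denom)[!bad]
  a <- (1 - conf_level) / 2
  q <- stats::quantile(icc, c(a, 1 - a), names = FALSE)
  tibble::tibble(
    target = target, scope = scope,
    point = stats::median(icc), ci_low = q[1], ci_high = q[2],
    n_draws = length(icc), n_excluded = n_excluded
  )
}

#' Classify an ICC point estimate on the Koo & Li scale
#'
#' Left-closed intervals: below 0.5 poor, \[0.5, 0.75) moderate,
#' \[0.75, 0.90) good, \[0.90, 1\] excellent. The verbal scale overlaps at
#' its boundaries in common usage; the left-closed convention used here is
#' recorded in reports.
#'
#' @param point Numeric vector of ICCs in \[0, 1\].
#' @param thresholds Named numeric: lower bounds of moderate, good,
#'   excellent.
#' @return A factor with levels poor < moderate < good < excellent.
#' @examples
#' classify_icc(c(0.40, 0.88, 1))
#' @export
classify_icc <- function(point,
                         thresholds = c(
                           moderate = 0.5, good = 0.75, excellent = 0.9
                         )) {
  stopifnot(
    all(point >= 0 & point <= 1),
    all(c("moderate", "good", "excellent") %in% names(thresholds))
  )
  cut(point,
    breaks = c(
      -Inf, thresholds["moderate"], thresholds["good"],
      thresholds["excellent"], Inf
    ),
    labels = c("poor", "moderate", "good", "excellent"),
    right = FALSE, ordered_result = TRUE
  )
}

#' Both ICCs of one fitted model, with categories
#'
#' @param fit A `zib_fit`.
#' @param conf_level Credible-interval mass.
#' @return A two-row tibble (inter and intra) with `category` appended.
#' @export
icc_estimates <- function(fit, conf_level = 0.95) {
  dplyr::bind_rows(
    icc_from_draws(fit, "inter", conf_level = conf_level),
    icc_from_draws(fit, "intra", conf_level = conf_level)
  ) |>
    dplyr::mutate(category = classify_icc(.data$point))
}

#' ICC of one global movement-quality domain
#'
#' Averages the global item (smoothness or interjoint coordination) over
#' all phases per (rater, video, round), then runs the same
#' fit-and-summarise pipeline as a phase.
#'
#' @param data A validated rating tibble (exclusion already applied).
#' @param item One of the schema's global items.
#' @param spec A [zib_spec()].
#' @param schema A [labeling_schema()].
#' @return A two-row ICC tibble as from [icc_estimates()].
#' @export
global_domain_icc <- function(data, item, spec = zib_spec(),
                              schema = drinking_task_schema()) {
  scores <- aggregate_global_scores(data, item, schema)
  fit <- fit_zib(scores, spec)
  icc_estimates(fit)
}

#' Full reliability analysis: every phase plus the global domains
#'
#' Applies the not-assessable exclusion, aggregates phase means (global
#' items kept out) and each global domain's overall score, fits the
#' zero-inflated beta mixed model once per scope, and returns inter- and
#' intra-rater ICCs with credible intervals and categories.
#'
#' @param data A validated rating tibble (raw; exclusion is applied here).
#' @param spec A [zib_spec()].
#' @param schema A [labeling_schema()].
#' @param quiet Suppress sampler output?
#' @return A list with `icc` (tibble, two rows per scope) and `fits`
#'   (named list of `zib_fit` objects).
#' @export
icc_analysis <- function(data, spec = zib_spec(),
                         schema = drinking_task_schema(), quiet = TRUE) {
  clean <- exclude_not_assessable(data)
  phase_tbl <- aggregate_phase_scores(clean, schema)
  scopes <- c(schema$phases, schema$global_items)
  fits <- list()
  for (ph in schema$phases) {
    fits[[ph]] <- fit_zib(
      dplyr::filter(phase_tbl, .data$phase == ph), spec,
      quiet = quiet
    )
  }
  for (it in schema$global_items) {
    fits[[it]] <- fit_zib(aggregate_global_scores(clean, it, schema), spec,
      quiet = quiet
    )
  }
  icc <- purrr::imap_dfr(fits, function(f, nm) {
    dplyr::mutate(icc_estimates(f), scope = nm)
  }) |>
    dplyr::mutate(
      scope = factor(.data$scope, levels = scopes),
      scope_type = ifelse(
        as.character(.data$scope) %in% schema$global_items,
        "global_domain", "phase"
      )
    ) |>
    dplyr::arrange(.data$target, .data$scope)
  list(icc = icc, fits = fits)
}

#' Format an ICC table the way reliability studies report them
#'
#' One row per target (inter/intra), one column per phase holding
#' `"ICC (low-high)"` strings, plus separate rows for the global domains.
#'
#' @param icc An ICC tibble from [icc_analysis()] or [icc_estimates()].
#' @param digits Digits for the formatted strings.
#' @return A tibble of formatted strings.
#' @export
icc_report <- function(icc, digits = 2) {
  fmt <- function(p, l, h) {
    sprintf(
      "%.*f (%.*f-%.*f)", digits, p, digits, l, digits, h
    )
  }
  icc |>
    dplyr::mutate(cell = fmt(.data$point, .data$ci_low, .data$ci_high)) |>
    dplyr::select("target", "scope", "cell") |>
    tidyr::pivot_wider(names_from = "scope", values_from = "cell")
}
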