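#' Parameters of the synthetic rating-data generator
#'
#' The generator draws, for each (rater r, video v, phase p, round t) cell,
#' a latent logit
#' \deqn{\eta = \mu_0 + a_v + b_r + c_{rv} + e_{rvpt}}
#' with independent normal effects for video severity (`sigma2_video`),
#' rater bias (`sigma2_rater`), rater-by-video consistency
#' (`sigma2_rater_video`) and round-to-round noise (`sigma2_round`). Each
#' item in the cell is then, with probability
#' \eqn{\mathrm{logistic}(\pi_0 - \lambda (a_v + b_r + c_{rv}))}, an exact 0
#' ("no compensation"); otherwise it is \eqn{100 \times} a
#' \eqn{\mathrm{Beta}(\mathrm{logistic}(\eta)\phi,
#' (1-\mathrm{logistic}(\eta))\phi)} draw. The shared loading
#' \eqn{\lambda} (`zero_effect_scale`) makes zeros more likely for mildly
#' affected videos and lenient raters; 0 gives independent zero-inflation.
#'
#' Global movement-quality items (smoothness, interjoint coordination) can
#' carry an attenuated video effect (`global_video_scale` < 1), reflecting
#' that judgements of global movement quality separate the videos less well
#' than segment-specific compensations; this is what drives their lower
#' true reliability.
#'
#' Not-assessable flags are generated per cell-item with base rate
#' `na_rate`, elevated to `na_focus_rate` for wrist/hand items during the
#' drinking phase (video anonymisation hides the hand near the face), and
#' correlated across rounds through a shared cell propensity
#' (`na_round_correlation`).
#'
#' @param n_raters,n_videos,n_rounds Design size (positive integers).
#' @param schema A [labeling_schema()].
#' @param mu_intercept Mean of the beta component, logit scale.
#' @param phi Beta precision (> 0).
#' @param pi_intercept Zero-inflation probability, logit scale.
#' @param sigma2_video,sigma2_rater,sigma2_rater_video,sigma2_round
#'   Variance components on the latent logit scale (>= 0).
#' @param zero_effect_scale Loading of the stable latent effects on the
#'   zero-inflation logit (>= 0).
#' @param global_video_scale Multiplier in \[0, 1\] applied to the video
#'   effect for global items.
#' @param na_rate,na_focus_rate Not-assessable probabilities per item
#'   rating (base, and for the focus cells).
#' @param na_round_correlation Correlation of the not-assessable propensity
#'   between rounds, in \[0, 1).
#' @param variance_targeting Logical; if `TRUE`, each realized vector of
#'   random effects is rescaled to have exactly its nominal variance
#'   (as `MASS::mvrnorm(empirical = TRUE)` does). Used by calibration
#'   studies so that the dataset's true reliability equals the nominal one
#'   instead of fluctuating with the few-videos design; leave `FALSE` for
#'   realistic data.
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   parameters and the seed.
#' @return An object of class `generator_params` (a validated list).
#' @seealso [simulate_ratings()], [true_icc_latent()], [true_icc_response()]
#' @export
generator_params <- function(n_raters = 22, n_videos = 7, n_rounds = 2,
                             schema = drinking_task_schema(),
                             mu_intercept = -1.1, phi = 5,
                             pi_intercept = 0.4,
                             sigma2_video = 1.0, sigma2_rater = 0.3,
                             sigma2_rater_video = 0.15, sigma2_round = 0.15,
                             zero_effect_scale = 1,
                             global_video_scale = 0.3,
                             na_rate = 0.006, na_focus_rate = 0.25,
                             na_round_correlation = 0.5,
                             variance_targeting = FALSE,
                             seed = 1L) {
  stopifnot(
    n_raters >= 1, n_videos >= 1, n_rounds >= 1,
    inherits(schema, "labeling_schema"),
    phi > 0,
    sigma2_video >= 0, sigma2_rater >= 0,
    sigma2_rater_video >= 0, sigma2_round >= 0,
    zero_effect_scale >= 0,
    global_video_scale >= 0, global_video_scale <= 1,
    na_rate >= 0, na_rate < 1, na_focus_rate >= 0, na_focus_rate < 1,
    na_round_correlation >= 0, na_round_correlation < 1
  )
  structure(
    list(
      n_raters = as.integer(n_raters), n_videos = as.integer(n_videos),
      n_rounds = as.integer(n_rounds), schema = schema,
      mu_intercept = mu_intercept, phi = phi, pi_intercept = pi_intercept,
      sigma2_video = sigma2_video, sigma2_rater = sigma2_rater,
      sigma2_rater_video = sigma2_rater_video, sigma2_round = sigma2_round,
      zero_effect_scale = zero_effect_scale,
      global_video_scale = global_video_scale,
      na_rate = na_rate, na_focus_rate = na_focus_rate,
      na_round_correlation = na_round_correlation,
      variance_targeting = isTRUE(variance_targeting),
      seed = as.integer(seed)
    ),
    class = "generator_params"
  )
}

#' Study-like generator preset
#'
#' Defaults sized to the reliability study design: 22 raters, 7 videos of
#' mildly-to-moderately impaired individuals, 2 labeling rounds and the
#' 55-field drinking-task schema. The latent parameters are chosen so that
#' roughly 60% of item ratings are exact zeros and positive ratings
#' concentrate in the lower third of the 0-100 scale.
#'
#' @param ... Overrides passed on to [generator_params()].
#' @return A `generator_params` object.
#' @export
study_preset <- function(...) {
  generator_params(...)
}

#' @export
print.generator_params <- function(x, ...) {
  cat("<generator_params>\n")
  cat(sprintf(
    "  design: %d raters x %d videos x %d rounds, %d fields/video\n",
    x$n_raters, x$n_videos, x$n_rounds,
    length(x$schema$phases) * length(x$schema$items)
  ))
  cat(sprintf(
    "  beta: mu_intercept=%.3g (logit), phi=%.3g; zero-inflation: pi_intercept=%.3g, loading=%.3g\n",
    x$mu_intercept, x$phi, x$pi_intercept, x$zero_effect_scale
  ))
  cat(sprintf(
    "  variances (logit): video=%.3g rater=%.3g rater:video=%.3g round=%.3g\n",
    x$sigma2_video, x$sigma2_rater, x$sigma2_rater_video, x$sigma2_round
  ))
  cat(sprintf(
    "  true latent ICC: inter=%.3f intra=%.3f\n",
    true_icc_latent(x)$icc_inter, true_icc_latent(x)$icc_intra
  ))
  invisible(x)
}

# rescale a draw vector to zero mean and exactly the nominal variance
.target_variance <- function(x, s2) {
  if (s2 == 0 || length(x) < 2) {
    return(x)
  }
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x * sqrt(s2) / s else x
}

#' Simulate a rating dataset with known reliability structure
#'
#' Draws a complete long-format rating table under the zero-inflated beta
#' latent model described in [generator_params()]. All values lie in
#' \[0, 100\]; zeros are exact; exact 100 never occurs (open-interval beta).
#' The result is byte-identical for a fixed parameter set and seed.
#'
#' @param params A [generator_params()] object.
#' @return A validated rating tibble (see [read_ratings()] for columns).
#' @examples
#' d <- simulate_ratings(generator_params(n_raters = 3, n_videos = 2, seed = 7))
#' dataset_dimensions(d)
#' @export
simulate_ratings <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  sch <- p$schema
  withr_seed <- p$seed
  old <- globalenv()$.Random.seed
  set.seed(withr_seed)
  on.exit(
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
    add = TRUE
  )

  raters <- sprintf("R%02d", seq_len(p$n_raters))
  videos <- sprintf("V%d", seq_len(p$n_videos))

  a_v <- stats::rnorm(p$n_videos, 0, sqrt(p$sigma2_video))
  b_r <- stats::rnorm(p$n_raters, 0, sqrt(p$sigma2_rater))
  c_rv <- matrix(
    stats::rnorm(p$n_raters * p$n_videos, 0, sqrt(p$sigma2_rater_video)),
    p$n_raters, p$n_videos
  )
  if (p$variance_targeting) {
    a_v <- .target_variance(a_v, p$sigma2_video)
    b_r <- .target_variance(b_r, p$sigma2_rater)
    c_rv[] <- .target_variance(as.vector(c_rv), p$sigma2_rater_video)
  }

  grid <- tidyr::expand_grid(
    rater = seq_len(p$n_raters),
    video = seq_len(p$n_videos),
    phase = sch$phases,
    round = seq_len(p$n_rounds)
  )
  e_cell <- stats::rnorm(nrow(grid), 0, sqrt(p$sigma2_round))
  if (p$variance_targeting) e_cell <- .target_variance(e_cell, p$sigma2_round)
  stable <- a_v[grid$video] + b_r[grid$rater] +
    c_rv[cbind(grid$rater, grid$video)]
  # per-cell latent for non-global items; global items attenuate the video
  # effect only (rater bias and consistency still apply)
  eta <- p$mu_intercept + stable + e_cell
  eta_g <- p$mu_intercept + p$global_video_scale * a_v[grid$video] +
    b_r[grid$rater] + c_rv[cbind(grid$rater, grid$video)] + e_cell
  stable_g <- p$global_video_scale * a_v[grid$video] + b_r[grid$rater] +
    c_rv[cbind(grid$rater, grid$video)]

  cells <- grid |>
    dplyr::mutate(
      eta = eta, eta_g = eta_g,
      pzero = stats::plogis(p$pi_intercept - p$zero_effect_scale * stable),
      pzero_g = stats::plogis(
        p$pi_intercept - p$zero_effect_scale * stable_g
      ),
      cell_id = dplyr::row_number()
    )

  long <- tidyr::expand_grid(cell_id = cells$cell_id, item = sch$items) |>
    dplyr::left_join(cells, by = "cell_id") |>
    dplyr::mutate(is_global = .data$item %in% sch$global_items)

  n <- nrow(long)
  mu <- stats::plogis(ifelse(long$is_global, long$eta_g, long$eta))
  pz <- ifelse(long$is_global, long$pzero_g, long$pzero)
  zero <- stats::rbinom(n, 1, pz) == 1
  value <- 100 * stats::rbeta(n, mu * p$phi, (1 - mu) * p$phi)
  value[zero] <- 0

  # not-assessable flags: shared cell-item propensity correlates rounds
  focus <- long$phase == "drinking" &
    long$item %in% c("wrist_flexion", "grasp_hand_opening")
  rate <- ifelse(focus, p$na_focus_rate, p$na_rate)
  rho <- p$na_round_correlation
  key <- paste(long$rater, long$video, long$phase, long$item, sep = "\r")
  z_cell <- stats::rnorm(length(unique(key)))
  names(z_cell) <- unique(key)
  w <- sqrt(rho) * z_cell[key] + sqrt(1 - rho) * stats::rnorm(n)
  na_flag <- w < stats::qnorm(rate)

  out <- tibble::tibble(
    rater_id = raters[long$rater],
    video_id = videos[long$video],
    phase = long$phase,
    item = long$item,
    round = as.integer(long$round),
    value = ifelse(na_flag, NA_real_, value),
    not_assessable = as.logical(na_flag)
  ) |>
    dplyr::arrange(
      .data$rater_id, .data$video_id, .data$phase, .data$item, .data$round
    )
  validate_ratings(out, sch)
}
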