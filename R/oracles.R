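#' True reliability of a generator parameter set, latent scale
#'
#' Closed-form intraclass correlations implied by the generator's variance
#' components on the latent logit scale:
#' \deqn{ICC_{inter} = \sigma^2_v / (\sigma^2_v + \sigma^2_r + \sigma^2_{rv}
#'   + \sigma^2_e)}
#' \deqn{ICC_{intra} = (\sigma^2_v + \sigma^2_r + \sigma^2_{rv}) /
#'   (\sigma^2_v + \sigma^2_r + \sigma^2_{rv} + \sigma^2_e)}
#' The inter-rater ICC is the correlation of two different raters' latent
#' scores for the same video; the intra-rater ICC is the test-retest
#' correlation of one rater on one video, so all cell-stable components
#' enter its numerator.
#'
#' @param params A [generator_params()] object.
#' @param global Logical; compute the ICC for the global movement-quality
#'   domains, whose video effect is attenuated by `global_video_scale`?
#' @return A tibble with columns `icc_inter`, `icc_intra`, `scale`.
#' @export
true_icc_latent <- function(params, global = FALSE) {
  stopifnot(inherits(params, "generator_params"))
  s2v <- params$sigma2_video *
    (if (global) params$global_video_scale^2 else 1)
  s2r <- params$sigma2_rater
  s2rv <- params$sigma2_rater_video
  s2e <- params$sigma2_round
  total <- s2v + s2r + s2rv + s2e
  if (total == 0) {
    stop("all variance components are zero: latent ICC undefined",
      call. = FALSE
    )
  }
  tibble::tibble(
    icc_inter = s2v / total,
    icc_intra = (s2v + s2r + s2rv) / total,
    scale = "latent"
  )
}

#' True reliability of a generator parameter set, response scale
#'
#' Monte-Carlo estimate of the intraclass correlations of the *observed*
#' 0-100 values (zeros included). For each of `n_mc` simulated videos, two
#' raters score the video in two rounds under the full generative model;
#' the inter-rater ICC is the correlation between different raters' scores
#' of the same video, the intra-rater ICC the correlation between one
#' rater's two rounds. Deterministic given `params$seed`.
#'
#' @inheritParams true_icc_latent
#' @param n_mc Number of Monte-Carlo videos (>= 1000).
#' @return A tibble with columns `icc_inter`, `icc_intra`, `scale`, and
#'   `degenerate` (`TRUE` when all variance components are zero, in which
#'   case both ICCs are 0 by convention).
#' @export
true_icc_response <- function(params, n_mc = 20000, global = FALSE) {
  stopifnot(inherits(params, "generator_params"), n_mc >= 1000)
  p <- params
  if (p$sigma2_video + p$sigma2_rater + p$sigma2_rater_video +
    p$sigma2_round == 0) {
    return(tibble::tibble(
      icc_inter = 0, icc_intra = 0, scale = "response", degenerate = TRUE
    ))
  }
  old <- globalenv()$.Random.seed
  set.seed(p$seed + 1L)
  on.exit(
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
    add = TRUE
  )
  gscale <- if (global) p$global_video_scale else 1

  a <- stats::rnorm(n_mc, 0, sqrt(p$sigma2_video))
  draw_rater <- function() {
    b <- stats::rnorm(n_mc, 0, sqrt(p$sigma2_rater))
    cc <- stats::rnorm(n_mc, 0, sqrt(p$sigma2_rater_video))
    stable <- gscale * a + b + cc
    draw_round <- function() {
      e <- stats::rnorm(n_mc, 0, sqrt(p$sigma2_round))
      eta <- p$mu_intercept + stable + e
      mu <- stats::plogis(eta)
      pz <- stats::plogis(p$pi_intercept - p$zero_effect_scale * stable)
      y <- 100 * stats::rbeta(n_mc, mu * p$phi, (1 - mu) * p$phi)
      y[stats::rbinom(n_mc, 1, pz) == 1] <- 0
      y
    }
    list(y1 = draw_round(), y2 = draw_round())
  }
  r1 <- draw_rater()
  r2 <- draw_rater()
  tibble::tibble(
    icc_inter = stats::cor(r1$y1, r2$y2),
    icc_intra = stats::cor(r1$y1, r1$y2),
    scale = "response",
    degenerate = FALSE
  )
}
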