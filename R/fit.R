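#' Specification of the zero-inflated beta mixed-effects model
#'
#' The model for one phase's (or one global domain's) scores, one row per
#' (rater, video, round):
#' \itemize{
#'   \item Each score is 0 with probability `logistic(pi_intercept)`
#'     (intercept-only zero-inflation by default; `zero_random_effects`
#'     adds a shared loading on the stable random effects).
#'   \item A positive score `y` has `squeeze(y / 100)` beta-distributed
#'     with mean `logistic(eta)` and precision `phi`, where
#'     `eta = mu_intercept + a_video + b_rater + c_rater_video + e_obs`.
#'   \item `e_obs` is an observation-level (one per rater-video-round cell)
#'     logit-scale effect whose variance is the round/test-retest
#'     component `sigma2_round`. The beta residual variance is
#'     mean-dependent and cannot enter a variance ratio, so the
#'     logit-scale effect is what makes intra-rater ICCs well defined.
#' }
#' Priors: half-normal(0, 1) on every variance-component standard
#' deviation, normal(0, 2.5) on the two intercepts, exponential(0.5) on
#' `phi` - weakly informative for logit-scale data on a bounded scale.
#'
#' @param random_effects Character subset of
#'   `c("video", "rater", "rater_video")`. `"video"` and `"rater"` are
#'   required for the ICCs to be meaningful; `"rater_video"` is included by
#'   default and dropped automatically when the data has a single round
#'   (it would be confounded with the observation-level effect).
#' @param zero_random_effects Logical; let the zero-inflation logit load on
#'   the stable random effects (mirrors the generator). Default `FALSE`:
#'   intercept-only zero-inflation keeps the model identifiable at the
#'   7-video study scale.
#' @param squeeze_epsilon Boundary squeeze in (0, 0.01] applied to scores
#'   of exactly 100 (and protecting 0 < y' < 1 generally).
#' @param chains Number of MCMC chains (>= 2).
#' @param warmup Adaptation + burn-in iterations per chain.
#' @param draws Kept draws per chain (>= 500).
#' @param thin Thinning interval.
#' @param seed Integer seed for the chains' RNGs.
#' @param rhat_threshold Split-R-hat above which the fit is flagged not
#'   converged.
#' @return An object of class `zib_spec`.
#' @export
zib_spec <- function(random_effects = c("video", "rater", "rater_video"),
                     zero_random_effects = FALSE,
                     squeeze_epsilon = 1e-4,
                     chains = 4, warmup = 1000, draws = 1000, thin = 1,
                     seed = 1L, rhat_threshold = 1.01) {
  random_effects <- match.arg(random_effects,
    c("video", "rater", "rater_video"),
    several.ok = TRUE
  )
  stopifnot(
    all(c("video", "rater") %in% random_effects),
    squeeze_epsilon > 0, squeeze_epsilon <= 0.01,
    chains >= 2, draws >= 500, warmup >= 0, thin >= 1
  )
  structure(
    list(
      random_effects = random_effects,
      zero_random_effects = isTRUE(zero_random_effects),
      squeeze_epsilon = squeeze_epsilon,
      chains = as.integer(chains), warmup = as.integer(warmup),
      draws = as.integer(draws), thin = as.integer(thin),
      seed = as.integer(seed), rhat_threshold = rhat_threshold
    ),
    class = "zib_spec"
  )
}

#' @export
print.zib_spec <- function(x, ...) {
  cat("<zib_spec>\n")
  cat("  random effects:", paste(x$random_effects, collapse = ", "),
    if (x$zero_random_effects) "(+ shared zero-inflation loading)" else "",
    "\n"
  )
  cat(sprintf(
    "  sampler: %d chains x (%d warmup + %d kept), thin %d, seed %d\n",
    x$chains, x$warmup, x$draws, x$thin, x$seed
  ))
  cat(sprintf(
    "  squeeze epsilon %g, R-hat threshold %g\n",
    x$squeeze_epsilon, x$rhat_threshold
  ))
  invisible(x)
}

# Assemble the BUGS model definition for the requested structure.
.zib_bugs_model <- function(use_rv, zero_re) {
  zero_logit <- if (zero_re) {
    "logit(pz[i]) <- pi0 - lambda * (a_v[zv[i]] + b_r[zr[i]]%s)"
  } else {
    "logit(pz[i]) <- pi0%s"
  }
  zero_logit <- sprintf(
    zero_logit,
    if (zero_re && use_rv) " + c_rv[zrv[i]]" else ""
  )
  rv_term <- if (use_rv) " + c_rv[rv[j]]" else ""
  rv_block <- if (use_rv) {
    "
  for (k in 1:NRV) { c_rv[k] ~ dnorm(0, tau_rv) }
  sd_rv ~ dnorm(0, 1) T(0,)
  tau_rv <- pow(sd_rv, -2)"
  } else {
    ""
  }
  lambda_block <- if (zero_re) {
    "
  lambda ~ dnorm(0, 0.16) T(0,)"
  } else {
    ""
  }
  sprintf("
model {
  for (i in 1:N) {
    zz[i] ~ dbern(pz[i])
    %s
  }
  for (j in 1:Npos) {
    ypos[j] ~ dbeta(mu[j] * phi, (1 - mu[j]) * phi)
    logit(mu[j]) <- b0 + a_v[v[j]] + b_r[r[j]]%s + e_obs[j]
    e_obs[j] ~ dnorm(0, tau_e)
  }
  for (k in 1:NV) { a_v[k] ~ dnorm(0, tau_v) }
  for (k in 1:NR) { b_r[k] ~ dnorm(0, tau_r) }
  b0 ~ dnorm(0, 0.16)
  pi0 ~ dnorm(0, 0.16)
  phi ~ dexp(0.5)
  sd_v ~ dnorm(0, 1) T(0,)
  sd_r ~ dnorm(0, 1) T(0,)
  sd_e ~ dnorm(0, 1) T(0,)
  tau_v <- pow(sd_v, -2)
  tau_r <- pow(sd_r, -2)
  tau_e <- pow(sd_e, -2)%s%s
}", zero_logit, rv_term, rv_block, lambda_block)
}

#' Fit the zero-inflated beta mixed model to one phase-level score table
#'
#' Runs MCMC (JAGS) for the model described in [zib_spec()] on a table of
#' phase-level mean scores for a single phase or global domain, as produced
#' by [aggregate_phase_scores()] or [aggregate_global_scores()].
#'
#' @param data A tibble with columns `rater_id`, `video_id`, `round`,
#'   `score` (0-100) covering exactly one phase (a `phase` column, if
#'   present, must be constant).
#' @param spec A [zib_spec()].
#' @param quiet Suppress JAGS progress output?
#' @return An object of class `zib_fit`: a list with
#'   \describe{
#'     \item{draws}{tibble, one row per kept draw: `chain`, `iter`,
#'       `sigma2_video`, `sigma2_rater`, `sigma2_rater_video` (0 when the
#'       term is omitted), `sigma2_round`, `mu_intercept`, `phi`,
#'       `pi_intercept`.}
#'     \item{diagnostics}{tibble of per-parameter split-R-hat and effective
#'       sample size.}
#'     \item{converged}{logical flag; `FALSE` raises a warning at fit
#'       time but still returns the draws.}
#'     \item{spec, scope, n_obs, n_zero}{metadata.}
#'   }
#' @export
fit_zib <- function(data, spec = zib_spec(), quiet = TRUE) {
  stopifnot(inherits(spec, "zib_spec"))
  data <- tibble::as_tibble(data)
  needed <- c("rater_id", "video_id", "round", "score")
  if (!all(needed %in% names(data))) {
    stop(
      "data must have columns ", paste(needed, collapse = ", "),
      call. = FALSE
    )
  }
  scope <- if ("phase" %in% names(data)) unique(data$phase) else NA_character_
  if (length(scope) > 1) {
    stop(
      "fit_zib() expects a single phase; got: ",
      paste(scope, collapse = ", "), ". Fit each phase separately ",
      "(see icc_analysis()).",
      call. = FALSE
    )
  }
  if (any(data$score < 0 | data$score > 100)) {
    stop("scores outside [0, 100]", call. = FALSE)
  }
  n_raters <- dplyr::n_distinct(data$rater_id)
  n_videos <- dplyr::n_distinct(data$video_id)
  if (n_raters < 2 || n_videos < 2) {
    stop("need at least 2 raters and 2 videos", call. = FALSE)
  }
  if (all(data$score == 0)) {
    stop(
      "all scores are zero: the beta component has no data and variance ",
      "components are unidentifiable",
      call. = FALSE
    )
  }
  n_rounds <- dplyr::n_distinct(data$round)
  use_rv <- "rater_video" %in% spec$random_effects && n_rounds >= 2

  rater <- as.integer(factor(data$rater_id))
  video <- as.integer(factor(data$video_id))
  rv <- as.integer(factor(paste(rater, video)))
  eps <- spec$squeeze_epsilon
  pos <- which(data$score > 0)
  ypos <- (data$score[pos] / 100) * (1 - 2 * eps) + eps

  jags_data <- list(
    N = nrow(data), zz = as.integer(data$score == 0),
    Npos = length(pos), ypos = ypos,
    v = video[pos], r = rater[pos],
    NV = n_videos, NR = n_raters
  )
  if (use_rv) {
    jags_data$rv <- rv[pos]
    jags_data$NRV <- max(rv)
  }
  if (spec$zero_random_effects) {
    jags_data$zv <- video
    jags_data$zr <- rater
    if (use_rv) jags_data$zrv <- rv
  }

  inits <- lapply(seq_len(spec$chains), function(i) {
    list(
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = spec$seed * 1000L + i
    )
  })
  model_txt <- .zib_bugs_model(use_rv, spec$zero_random_effects)
  monitor <- c("sd_v", "sd_r", "sd_e", "b0", "phi", "pi0")
  if (use_rv) monitor <- c(monitor, "sd_rv")

  n_adapt <- max(100L, spec$warmup %/% 2L)
  n_burn <- spec$warmup - n_adapt
  model <- rjags::jags.model(
    textConnection(model_txt),
    data = jags_data, inits = inits,
    n.chains = spec$chains, n.adapt = n_adapt, quiet = quiet
  )
  if (n_burn > 0) update(model, n_burn, progress.bar = "none")
  samples <- rjags::coda.samples(
    model, monitor,
    n.iter = spec$draws * spec$thin, thin = spec$thin,
    progress.bar = "none"
  )

  draws <- purrr::imap_dfr(samples, function(ch, i) {
    m <- as.matrix(ch)
    tibble::tibble(
      chain = as.integer(i), iter = seq_len(nrow(m)),
      sigma2_video = m[, "sd_v"]^2,
      sigma2_rater = m[, "sd_r"]^2,
      sigma2_rater_video = if (use_rv) m[, "sd_rv"]^2 else 0,
      sigma2_round = m[, "sd_e"]^2,
      mu_intercept = m[, "b0"],
      phi = m[, "phi"],
      pi_intercept = m[, "pi0"]
    )
  })

  diagnostics <- .zib_diagnostics(samples)
  converged <- all(diagnostics$rhat <= spec$rhat_threshold, na.rm = TRUE)
  if (!converged) {
    warning(
      "fit did not converge (max split R-hat ",
      sprintf("%.3f", max(diagnostics$rhat, na.rm = TRUE)),
      " > ", spec$rhat_threshold, "); interpret with caution",
      call. = FALSE
    )
  }

  structure(
    list(
      draws = draws, diagnostics = diagnostics, converged = converged,
      spec = spec, scope = scope, n_obs = nrow(data),
      n_zero = sum(data$score == 0), n_raters = n_raters,
      n_videos = n_videos, n_rounds = n_rounds, use_rater_video = use_rv
    ),
    class = "zib_fit"
  )
}

# split-R-hat and ESS for an mcmc.list
.zib_diagnostics <- function(samples) {
  params <- colnames(samples[[1]])
  rhat <- vapply(params, function(p) {
    chains <- lapply(samples, function(ch) as.numeric(ch[, p]))
    split_rhat(chains)
  }, numeric(1))
  ess <- tryCatch(
    coda::effectiveSize(samples)[params],
    error = function(e) rep(NA_real_, length(params))
  )
  tibble::tibble(
    term = .canonical_term(params),
    rhat = unname(rhat),
    ess = unname(as.numeric(ess))
  )
}

.canonical_term <- function(params) {
  map <- c(
    sd_v = "sigma_video", sd_r = "sigma_rater", sd_rv = "sigma_rater_video",
    sd_e = "sigma_round", b0 = "mu_intercept", phi = "phi",
    pi0 = "pi_intercept", lambda = "zero_loading"
  )
  out <- map[params]
  out[is.na(out)] <- params[is.na(out)]
  unname(out)
}

#' Split-R-hat of a set of chains
#'
#' Potential scale reduction factor computed after splitting each chain
#' into halves, so within-chain drift shows up as apparent
#' non-convergence. The conservative form
#' \eqn{\hat R = \sqrt{1 + B/(nW)}} is used (between-half-chain variance
#' \eqn{B}, within variance \eqn{W}): it is at least 1 by construction and
#' exactly 1 when every half-chain has the same mean.
#'
#' @param chains A list of numeric vectors (one per chain, equal length).
#' @return The split-R-hat (scalar). `NA` if the draws are constant.
#' @export
split_rhat <- function(chains) {
  stopifnot(is.list(chains), length(chains) >= 1)
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2
    list(x[seq_len(n)], x[(length(x) - n + 1):length(x)])
  }), recursive = FALSE)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  w <- mean(vars)
  b <- n * stats::var(means)
  if (!is.finite(w) || w == 0) {
    return(if (b == 0) 1 else NA_real_)
  }
  sqrt(1 + b / (n * w))
}

#' Convergence diagnostics of a fitted model
#'
#' @param fit A `zib_fit`.
#' @param rhat_threshold Override the spec's R-hat threshold.
#' @param min_ess Minimum acceptable effective sample size.
#' @return A tibble of per-parameter `rhat` and `ess` with a `pass` column,
#'   and attribute `"pass"` giving the overall verdict.
#' @export
convergence_report <- function(fit, rhat_threshold = NULL, min_ess = 100) {
  stopifnot(inherits(fit, "zib_fit"))
  thr <- rhat_threshold %||% fit$spec$rhat_threshold
  out <- fit$diagnostics |>
    dplyr::mutate(
      pass = (is.na(.data$rhat) | .data$rhat <= thr) &
        (is.na(.data$ess) | .data$ess >= min_ess)
    )
  attr(out, "pass") <- all(out$pass)
  out
}

#' @export
print.zib_fit <- function(x, ...) {
  cat("<zib_fit>",
    if (!is.na(x$scope)) paste0(" scope: ", x$scope), "\n",
    sep = ""
  )
  cat(sprintf(
    "  %d obs (%d zero) from %d raters x %d videos x %d rounds\n",
    x$n_obs, x$n_zero, x$n_raters, x$n_videos, x$n_rounds
  ))
  cat(sprintf(
    "  %d draws (%d chains); converged: %s\n",
    nrow(x$draws), x$spec$chains, x$converged
  ))
  print(tidy(x))
  invisible(x)
}

#' Tidy posterior summaries of a fitted zero-inflated beta mixed model
#'
#' @param x A `zib_fit`.
#' @param conf_level Credible-interval mass.
#' @param ... Unused.
#' @return A tibble with one row per parameter: posterior median
#'   (`estimate`), standard deviation (`std.error`), equal-tailed interval
#'   bounds, split-R-hat and effective sample size.
#' @method tidy zib_fit
#' @export
tidy.zib_fit <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  pars <- c(
    "sigma2_video", "sigma2_rater", "sigma2_rater_video", "sigma2_round",
    "mu_intercept", "phi", "pi_intercept"
  )
  sum_tbl <- x$draws |>
    tidyr::pivot_longer(dplyr::all_of(pars),
      names_to = "term", values_to = "value"
    ) |>
    dplyr::summarise(
      estimate = stats::median(.data$value),
      std.error = stats::sd(.data$value),
      conf.low = stats::quantile(.data$value, a),
      conf.high = stats::quantile(.data$value, 1 - a),
      .by = "term"
    )
  diag_tbl <- x$diagnostics |>
    dplyr::mutate(term = dplyr::case_match(.data$term,
      "sigma_video" ~ "sigma2_video",
      "sigma_rater" ~ "sigma2_rater",
      "sigma_rater_video" ~ "sigma2_rater_video",
      "sigma_round" ~ "sigma2_round",
      .default = .data$term
    ))
  dplyr::left_join(sum_tbl, diag_tbl, by = "term")
}

#' One-row summary of a fitted zero-inflated beta mixed model
#'
#' @inheritParams tidy.zib_fit
#' @return A one-row tibble: data size, draw count, convergence flag,
#'   worst R-hat and smallest effective sample size.
#' @method glance zib_fit
#' @export
glance.zib_fit <- function(x, ...) {
  tibble::tibble(
    scope = x$scope, n_obs = x$n_obs, n_zero = x$n_zero,
    n_raters = x$n_raters, n_videos = x$n_videos, n_rounds = x$n_rounds,
    n_draws = nrow(x$draws), chains = x$spec$chains,
    converged = x$converged,
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE)
  )
}
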