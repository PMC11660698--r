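test_that("generated values are bounded, zeros exact and 100 unreachable", {
  d <- simulate_ratings(generator_params(
    n_raters = 5, n_videos = 3, seed = 42
  ))
  v <- d$value[!d$not_assessable]
  expect_true(all(v >= 0 & v <= 100))
  expect_gt(sum(v == 0), 0)
  expect_true(all(v < 100 | v == 0))
  expect_false(any(v == 100))
})

test_that("a fixed seed reproduces the dataset exactly", {
  p <- generator_params(n_raters = 4, n_videos = 3, seed = 99)
  expect_identical(simulate_ratings(p), simulate_ratings(p))
  p2 <- generator_params(n_raters = 4, n_videos = 3, seed = 100)
  expect_false(identical(simulate_ratings(p), simulate_ratings(p2)))
})

test_that("extreme zero-inflation intercept forces every value to zero", {
  d <- simulate_ratings(generator_params(
    n_raters = 3, n_videos = 2, pi_intercept = 20,
    na_rate = 0, na_focus_rate = 0, seed = 1
  ))
  expect_true(all(d$value == 0))
})

test_that("with no latent effects the zero fraction matches the binomial
           oracle", {
  # logistic(0) = 0.5; >16k Bernoulli draws, 3 Monte-Carlo SEs
  d <- simulate_ratings(generator_params(
    sigma2_video = 0, sigma2_rater = 0, sigma2_rater_video = 0,
    sigma2_round = 0, zero_effect_scale = 0, pi_intercept = 0,
    na_rate = 0, na_focus_rate = 0, seed = 7
  ))
  n <- nrow(d)
  expect_gte(n, 10000)
  expect_lt(abs(mean(d$value == 0) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("between-video spread of cell means grows with sigma2_video", {
  spread <- purrr::map_dbl(c(0.2, 0.8, 2.0), function(s2) {
    d <- simulate_ratings(generator_params(
      n_raters = 8, n_videos = 7, sigma2_video = s2,
      pi_intercept = -1, zero_effect_scale = 0,
      na_rate = 0, na_focus_rate = 0, seed = 123
    ))
    d |>
      dplyr::summarise(m = mean(value), .by = video_id) |>
      dplyr::pull(m) |>
      var()
  })
  expect_true(all(diff(spread) > 0))
})

test_that("latent-scale oracle reproduces the closed-form ratios", {
  base <- function(...) {
    generator_params(..., na_rate = 0, na_focus_rate = 0)
  }
  p1 <- base(sigma2_video = 1, sigma2_rater = 0, sigma2_rater_video = 0,
    sigma2_round = 0)
  expect_equal(true_icc_latent(p1)$icc_inter, 1)
  p2 <- base(sigma2_video = 1, sigma2_rater = 1, sigma2_rater_video = 0,
    sigma2_round = 2)
  expect_equal(true_icc_latent(p2)$icc_inter, 0.25)
  expect_equal(true_icc_latent(p2)$icc_intra, 0.5)
  p3 <- base(sigma2_video = 0.3, sigma2_rater = 0.7,
    sigma2_rater_video = 0.2, sigma2_round = 0)
  expect_equal(true_icc_latent(p3)$icc_intra, 1)
  p0 <- base(sigma2_video = 0, sigma2_rater = 0, sigma2_rater_video = 0,
    sigma2_round = 0)
  expect_error(true_icc_latent(p0), "undefined")
})

test_that("response-scale oracle: degenerate convention and Gaussian limit", {
  p0 <- generator_params(
    sigma2_video = 0, sigma2_rater = 0, sigma2_rater_video = 0,
    sigma2_round = 0, seed = 5
  )
  r0 <- true_icc_response(p0)
  expect_true(r0$degenerate)
  expect_equal(r0$icc_inter, 0)
  expect_equal(r0$icc_intra, 0)

  # no zeros and small variances: the logit transform is nearly linear, so
  # the response-scale ICC matches a Gaussian-on-logit delta-method oracle
  # in which the beta noise contributes 1 / (phi * mu * (1 - mu)) of
  # latent-equivalent variance to the denominator
  p <- generator_params(
    pi_intercept = -20, phi = 5000,
    sigma2_video = 0.01, sigma2_rater = 0.005,
    sigma2_rater_video = 0.0025, sigma2_round = 0.0025,
    zero_effect_scale = 0, seed = 31
  )
  mu0 <- plogis(p$mu_intercept)
  noise <- 1 / (p$phi * mu0 * (1 - mu0))
  tot <- p$sigma2_video + p$sigma2_rater + p$sigma2_rater_video +
    p$sigma2_round + noise
  analytic_inter <- p$sigma2_video / tot
  analytic_intra <- (p$sigma2_video + p$sigma2_rater +
    p$sigma2_rater_video) / tot
  resp <- true_icc_response(p, n_mc = 50000)
  expect_lt(abs(resp$icc_inter - analytic_inter), 0.02)
  expect_lt(abs(resp$icc_intra - analytic_intra), 0.02)
})

test_that("latent and response oracles agree on ordering across a grid", {
  grid <- c(0.1, 0.4, 1.0, 2.0)
  lat <- numeric(length(grid))
  resp <- numeric(length(grid))
  for (i in seq_along(grid)) {
    p <- generator_params(
      sigma2_video = grid[i], sigma2_rater = 0.2,
      sigma2_rater_video = 0.1, sigma2_round = 0.1,
      pi_intercept = -1, zero_effect_scale = 0, seed = 17
    )
    lat[i] <- true_icc_latent(p)$icc_inter
    resp[i] <- true_icc_response(p, n_mc = 30000)$icc_inter
  }
  expect_true(all(diff(lat) > 0))
  # monotone within Monte-Carlo error
  expect_true(all(diff(resp) > -0.02))
})

test_that("variance targeting pins the realized effect variances", {
  # in the noise-free limit (no zeros, enormous precision, only the video
  # component) the latent video effect is recoverable from the logit of
  # the observed value, so its realized sample variance is checkable
  for (seed in c(3, 4)) {
    p <- generator_params(
      n_raters = 2, n_videos = 10, n_rounds = 1, schema = scalar_schema(),
      pi_intercept = -30, phi = 1e7, zero_effect_scale = 0,
      sigma2_video = 0.5, sigma2_rater = 0, sigma2_rater_video = 0,
      sigma2_round = 0, na_rate = 0, na_focus_rate = 0,
      variance_targeting = TRUE, seed = seed
    )
    d <- simulate_ratings(p)
    a_hat <- d |>
      dplyr::summarise(
        a = mean(qlogis(value / 100)) - p$mu_intercept, .by = video_id
      )
    expect_equal(var(a_hat$a), 0.5, tolerance = 1e-2)
    expect_equal(mean(a_hat$a), 0, tolerance = 1e-2)
  }
})

test_that("not-assessable flags concentrate where the preset says and
           correlate across rounds", {
  d <- simulate_ratings(generator_params(seed = 2))
  tal <- not_assessable_tally(d)
  top <- tal$by_field |>
    dplyr::summarise(n = sum(n_flags), .by = c(phase, item)) |>
    dplyr::arrange(dplyr::desc(n))
  expect_equal(unique(top$phase[1:2]), "drinking")
  expect_setequal(
    top$item[1:2], c("wrist_flexion", "grasp_hand_opening")
  )
  expect_true(all(tal$by_round$n_flags > 0))
})
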