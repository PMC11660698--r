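#' Zero-inflated beta log-density on the 0-100 slider scale
#'
#' Density of the mixture of a point mass at 0 (probability `pi`) and a
#' rescaled beta distribution on (0, 100): a value `y > 0` maps to
#' `y' = squeeze(y / 100)` with shape parameters `mu * phi` and
#' `(1 - mu) * phi`, where `squeeze(u) = u * (1 - 2 * epsilon) + epsilon`
#' keeps boundary values inside the open unit interval. The Jacobian of the
#' value-to-unit-interval map, `(1 - 2 * epsilon) / 100`, is included so
#' the density integrates to 1 over `{0} U (0, 100]` (up to the
#' epsilon-tail mass the squeeze excises).
#'
#' @param value Numeric vector of ratings in \[0, 100\].
#' @param pi Zero-inflation probability in \[0, 1\].
#' @param mu Beta mean in (0, 1).
#' @param phi Beta precision, > 0.
#' @param epsilon Boundary squeeze, in (0, 0.01\].
#' @param log Return the log density?
#' @return Numeric vector of (log-)densities.
#' @examples
#' zib_density(0, pi = 0.3, mu = 0.4, phi = 5) # exp of log(0.3)
#' @export
zib_density <- function(value, pi, mu, phi, epsilon = 1e-4, log = FALSE) {
  stopifnot(
    all(pi >= 0 & pi <= 1), all(mu > 0 & mu < 1), all(phi > 0),
    epsilon > 0, epsilon <= 0.01
  )
  if (any(value < 0 | value > 100)) {
    stop("value outside [0, 100]", call. = FALSE)
  }
  n <- max(length(value), length(pi), length(mu), length(phi))
  value <- rep_len(value, n)
  pi <- rep_len(pi, n)
  mu <- rep_len(mu, n)
  phi <- rep_len(phi, n)
  out <- numeric(n)
  zero <- value == 0
  out[zero] <- log(pi[zero])
  if (any(!zero)) {
    yp <- (value[!zero] / 100) * (1 - 2 * epsilon) + epsilon
    out[!zero] <- log1p(-pi[!zero]) +
      stats::dbeta(yp, mu[!zero] * phi[!zero],
        (1 - mu[!zero]) * phi[!zero],
        log = TRUE
      ) +
      log((1 - 2 * epsilon) / 100)
  }
  if (log) out else exp(out)
}

#' @rdname zib_density
#' @details `zib_loglik()` is the model log-likelihood used in fitting: it
#'   evaluates the beta component on the squeezed unit interval without the
#'   constant 0-100 Jacobian term, so with `pi = 0` it coincides exactly
#'   with a plain beta-regression log-likelihood. It differs from
#'   `sum(zib_density(..., log = TRUE))` only by
#'   `n_positive * log((1 - 2 * epsilon) / 100)`, a constant in the
#'   parameters.
#' @export
zib_loglik <- function(value, pi, mu, phi, epsilon = 1e-4) {
  ll <- zib_density(value, pi, mu, phi, epsilon, log = TRUE)
  n <- max(length(value), length(pi), length(mu), length(phi))
  npos <- sum(rep_len(value, n) > 0)
  sum(ll) - npos * log((1 - 2 * epsilon) / 100)
}
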