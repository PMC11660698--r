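#' Approximate confidence-interval width for an ICC (Bonett)
#'
#' Bonett's large-sample variance of an intraclass correlation estimate
#' with `n_subjects` subjects and `k_ratings` ratings per subject,
#' \deqn{\mathrm{Var}(\hat\rho) \approx \frac{2 (1-\rho)^2 (1 + (k-1)\rho)^2}
#'   {k (k-1) (n-1)},}
#' turned into the width of the approximate `1 - alpha` interval,
#' `2 z sqrt(Var)`. Used for precision-based planning: how many raters are
#' needed before the interval around an expected ICC is usefully narrow.
#'
#' @param rho Expected ICC, in \[0, 1).
#' @param n_subjects Number of subjects (here: videos), >= 2.
#' @param k_ratings Number of ratings per subject (here: raters), >= 2.
#' @param alpha Significance level.
#' @return The approximate CI width (scalar, vectorised over inputs).
#' @export
bonett_ci_width <- function(rho, n_subjects, k_ratings, alpha = 0.05) {
  stopifnot(all(n_subjects >= 2), all(k_ratings >= 2), all(rho >= 0 & rho < 1))
  z <- stats::qnorm(1 - alpha / 2)
  v <- 2 * (1 - rho)^2 * (1 + (k_ratings - 1) * rho)^2 /
    (k_ratings * (k_ratings - 1) * (n_subjects - 1))
  2 * z * sqrt(v)
}

#' Smallest rater panel achieving a target ICC interval width
#'
#' Integer search for the smallest number of raters `k` such that
#' [bonett_ci_width()] at the expected ICC is at most `ci_width`, with the
#' videos as subjects. Returns the search trace so the achieved width at
#' every candidate is inspectable.
#'
#' @param expected_icc Expected reliability, in (0, 1).
#' @param ci_width Target confidence-interval width, in (0, 1).
#' @param alpha Significance level.
#' @param n_subjects Number of subjects (videos).
#' @param k_max Upper bound of the search.
#' @return An object of class `rater_requirement`: list with `k_required`,
#'   `achieved_width`, the input spec, and `trace` (tibble of `k`,
#'   `width`).
#' @examples
#' required_raters(expected_icc = 0.85, ci_width = 0.3, n_subjects = 7)
#' @export
required_raters <- function(expected_icc, ci_width, alpha = 0.05,
                            n_subjects = 7, k_max = 10000) {
  stopifnot(
    expected_icc > 0, expected_icc < 1,
    ci_width > 0, ci_width < 1, alpha > 0, alpha < 1, n_subjects >= 2
  )
  ks <- 2:k_max
  widths <- bonett_ci_width(expected_icc, n_subjects, ks, alpha)
  hit <- which(widths <= ci_width)
  if (length(hit) == 0) {
    stop(
      "no rater count up to ", k_max, " achieves width ", ci_width,
      call. = FALSE
    )
  }
  k <- ks[hit[1]]
  structure(
    list(
      k_required = k,
      achieved_width = widths[hit[1]],
      expected_icc = expected_icc, ci_width = ci_width,
      alpha = alpha, n_subjects = n_subjects,
      trace = tibble::tibble(
        k = ks[seq_len(min(hit[1] + 5, length(ks)))],
        width = widths[seq_len(min(hit[1] + 5, length(ks)))]
      )
    ),
    class = "rater_requirement"
  )
}

#' @export
print.rater_requirement <- function(x, ...) {
  cat("<rater_requirement>\n")
  cat(sprintf(
    "  expected ICC %.2f, target width %.2f, alpha %.2f, %d subjects\n",
    x$expected_icc, x$ci_width, x$alpha, x$n_subjects
  ))
  cat(sprintf(
    "  required raters: %d (achieved width %.4f)\n",
    x$k_required, x$achieved_width
  ))
  invisible(x)
}

#' Inflate a recruitment target for expected dropout
#'
#' Multiplicative redundancy: `ceiling(n * (1 + dropout_rate))`, so 20
#' raters with 25% redundancy become 25 recruits.
#'
#' @param n Required number after dropout (>= 1).
#' @param dropout_rate Expected dropout fraction, in \[0, 1).
#' @return Integer recruitment target.
#' @examples
#' inflate_for_dropout(20, 0.25)
#' @export
inflate_for_dropout <- function(n, dropout_rate) {
  stopifnot(n >= 1, dropout_rate >= 0, dropout_rate < 1)
  as.integer(ceiling(n * (1 + dropout_rate)))
}

#' Study-design summary: rater requirement plus recruitment target
#'
#' @inheritParams required_raters
#' @param dropout_rate Expected dropout fraction.
#' @return A one-row tibble with the spec, the required panel and the
#'   inflated recruitment number.
#' @export
design_summary <- function(expected_icc = 0.85, ci_width = 0.3,
                           alpha = 0.05, n_subjects = 7,
                           dropout_rate = 0.25) {
  req <- required_raters(expected_icc, ci_width, alpha, n_subjects)
  tibble::tibble(
    expected_icc = expected_icc, ci_width = ci_width, alpha = alpha,
    n_subjects = n_subjects, dropout_rate = dropout_rate,
    k_required = req$k_required,
    achieved_width = req$achieved_width,
    n_recruit = inflate_for_dropout(req$k_required, dropout_rate)
  )
}
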