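#' Scatterplot of round 1 against round 2 ratings per phase
#'
#' One panel per phase; each point is one (rater, video, item) pair of
#' ratings. Mass on the axes shows pairs where a movement was scored 0 in
#' one round but positive in the other; the pile at the origin is the
#' zero-concordant "no compensation in either round" agreement.
#'
#' @param data A rating tibble with both rounds (exclusion applied).
#' @return A ggplot object.
#' @export
plot_round_agreement <- function(data) {
  pairs <- paired_rounds(data)
  counts <- zero_concordance(data) |>
    dplyr::mutate(
      label = sprintf("n = %d\nboth 0: %d", .data$n_pairs, .data$n_both_zero)
    )
  ggplot2::ggplot(
    pairs,
    ggplot2::aes(x = .data$value_1, y = .data$value_2)
  ) +
    ggplot2::geom_abline(
      slope = 1, intercept = 0, linetype = 2, colour = "grey60"
    ) +
    ggplot2::geom_point(alpha = 0.25, size = 0.8) +
    ggplot2::geom_text(
      data = counts,
      ggplot2::aes(label = .data$label),
      x = 5, y = 95, hjust = 0, vjust = 1, size = 3, inherit.aes = FALSE
    ) +
    ggplot2::facet_wrap(~phase) +
    ggplot2::coord_fixed(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::labs(
      x = "round 1 rating", y = "round 2 rating",
      title = "Round-to-round agreement of compensation ratings"
    ) +
    ggplot2::theme_minimal()
}

#' Plot ICC estimates with credible intervals
#'
#' Point estimates and 95% credible intervals per scope, split by
#' inter-/intra-rater target, with the Koo & Li category boundaries as
#' reference lines.
#'
#' @param icc An ICC tibble from [icc_analysis()] or [icc_estimates()].
#' @return A ggplot object.
#' @export
plot_icc <- function(icc) {
  ggplot2::ggplot(
    icc,
    ggplot2::aes(
      x = .data$point, y = .data$scope, colour = .data$target
    )
  ) +
    ggplot2::geom_vline(
      xintercept = c(0.5, 0.75, 0.9), linetype = 3, colour = "grey50"
    ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "ICC (95% credible interval)", y = NULL, colour = NULL,
      title = "Inter- and intra-rater reliability",
      caption = "dotted lines: poor / moderate / good / excellent boundaries"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot zib_fit
#' @export
autoplot.zib_fit <- function(object, ...) {
  pars <- c(
    "sigma2_video", "sigma2_rater", "sigma2_rater_video", "sigma2_round"
  )
  long <- object$draws |>
    tidyr::pivot_longer(dplyr::all_of(pars),
      names_to = "component", values_to = "value"
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::facet_wrap(~component, scales = "free") +
    ggplot2::labs(
      x = "posterior draw (logit-scale variance)", y = "density",
      title = paste0(
        "Posterior variance components",
        if (!is.na(object$scope)) paste0(" - ", object$scope)
      )
    ) +
    ggplot2::theme_minimal()
}
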