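#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a delta-l screen
#'
#' Ranked delta-l values with the selected (top-k) probes highlighted.
#'
#' @param object A `screen_result` from [screen_sites()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.screen_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = .data$delta_l,
                                       colour = .data$selected)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "grey50"),
                                 name = "selected") +
    ggplot2::labs(x = "rank", y = expression(Delta * italic(l)),
                  title = "Mendelian screen") +
    ggplot2::theme_minimal()
}

#' Plot a SNP-proximity trend
#'
#' Binned proportions of near-SNP probes (with exact binomial 95 percent CIs)
#' against delta-l, with the fitted logistic-polynomial curve.
#'
#' @param object A `snp_trend` from [snp_trend_test()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.snp_trend <- function(object, ...) {
  dl <- object$fit$model$dl
  grid <- data.frame(dl = seq(min(dl), max(dl), length.out = 200))
  grid$p <- stats::predict(object$fit, newdata = grid, type = "response")
  ggplot2::ggplot(object$binned,
                  ggplot2::aes(x = .data$delta_l_mid, y = .data$prop_near_snp)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$dl, y = .data$p),
                       colour = "#2166ac") +
    ggplot2::labs(x = expression(Delta * italic(l)),
                  y = "proportion of probes near a known SNP",
                  title = sprintf("SNP-proximity trend (LRT p = %.2g)",
                                  object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot one site's M-values coloured by carrier probability
#'
#' @param site Site tibble (`individual_id`, `m`).
#' @param carriers Tibble from [carrier_posteriors()].
#' @return A ggplot.
#' @export
plot_site_carriers <- function(site, carriers) {
  dat <- dplyr::inner_join(site, carriers, by = "individual_id")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$m, y = .data$q1,
                                    colour = .data$family_id)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "M-value", y = "posterior carrier probability") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
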