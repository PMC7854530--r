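#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of fixed-effect prevalence ratios
#'
#' Point = PR (exponentiated posterior-mean coefficient), bar = 95% HPDI
#' on the PR scale, dashed line at PR = 1 (no association). The intercept
#' is dropped: it is a baseline rate, not a ratio.
#'
#' @param object An `nh_glmm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nh_glmm <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$term != "(Intercept)", ]
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pr, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Prevalence ratio (95% HPDI)", y = NULL,
                  title = "Deficiency-scope prevalence ratios") +
    ggplot2::theme_minimal()
}

#' Concentration indices across HRRs
#'
#' HHI vs affiliation-accounted HHI per HRR and date; points above the
#' identity line show the concentration added by super-organization
#' (delta-HHI).
#'
#' @param metrics Tibble from [compute_hrr_metrics()].
#' @return A ggplot.
#' @export
plot_concentration <- function(metrics) {
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data$hhi, y = .data$ahhi)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~date, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "HHI", y = "Affiliation-accounted HHI",
                  title = "Bed-share concentration per HRR") +
    ggplot2::theme_minimal()
}

#' Prevalence of super-organization across HRRs
#'
#' @param metrics Tibble from [compute_hrr_metrics()].
#' @return A ggplot histogram of per-HRR multiple-affiliation prevalence,
#'   faceted by processing date.
#' @export
plot_prevalence <- function(metrics) {
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data$prevalence_multiple_pct)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~date, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Multiple-affiliation prevalence (%)", y = "HRRs",
                  title = "Super-organization prevalence per HRR") +
    ggplot2::theme_minimal()
}
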