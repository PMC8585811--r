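#' Plot posterior diet proportions
#'
#' Boxplot-style summary of the posterior draws per source: median, credible
#' interval and full range, the standard way mixing-model output is shown.
#'
#' @param object A `diet_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diet_fit <- function(object, ...) {
  smry <- summarize_posterior(object)
  ggplot2::ggplot(smry, ggplot2::aes(x = .data$source)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$range_min,
                                         ymax = .data$range_max),
                            linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$ci_lower,
                                         ymax = .data$ci_upper),
                            linewidth = 1.4) +
    ggplot2::geom_point(ggplot2::aes(y = .data$median), size = 2.4) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Diet proportion",
                  title = sprintf("Posterior diet composition (%s model)",
                                  object$suite$kind)) +
    ggplot2::theme_minimal()
}

#' Plot an NMDS ordination
#'
#' @param object An `nmds_result`.
#' @param ... Unused.
#' @return A ggplot object with samples coloured by group and the stress in
#'   the subtitle.
#' @export
autoplot.nmds_result <- function(object, ...) {
  tb <- object$coordinates
  p <- ggplot2::ggplot(tb, ggplot2::aes(x = .data$axis1, y = .data$axis2))
  if ("group" %in% names(tb)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p +
    ggplot2::labs(x = "NMDS1", y = "NMDS2",
                  subtitle = sprintf("Kruskal stress = %.3f", object$stress)) +
    ggplot2::theme_minimal()
}

#' Posterior density plot per source
#'
#' @param fit A `diet_fit`.
#' @return A ggplot object of overlaid posterior densities.
#' @export
plot_posterior_density <- function(fit) {
  stopifnot(inherits(fit, "diet_fit"))
  long <- posterior_long(fit) |>
    dplyr::filter(startsWith(.data$parameter, "p["))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value,
                                     colour = .data$parameter,
                                     fill = .data$parameter)) +
    ggplot2::geom_density(alpha = 0.2) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "Diet proportion", y = "Posterior density",
                  colour = "Source", fill = "Source") +
    ggplot2::theme_minimal()
}

#' Trace plot of the MCMC chains
#'
#' @param fit A `diet_fit`.
#' @return A ggplot object, one facet per parameter, coloured by chain.
#' @export
plot_traces <- function(fit) {
  stopifnot(inherits(fit, "diet_fit"))
  long <- posterior_long(fit)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value,
                                     colour = factor(.data$chain))) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(colour = "Chain", x = "Kept iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
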