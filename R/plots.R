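#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col labs
#'   autoplot theme_minimal facet_wrap geom_vline geom_hline
NULL

#' Plot methods for package objects
#'
#' `autoplot()` methods give quick diagnostic figures: prior densities,
#' escort response functions, Fisher-information allocations, encoder Fisher
#' curves, and per-bin estimation summaries.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name fitmax-autoplot
NULL

#' @rdname fitmax-autoplot
#' @export
autoplot.fm_prior <- function(object, ...) {
  ggplot(object, aes(x = .data$s, y = .data$density)) +
    geom_line(color = "steelblue") +
    labs(x = "stimulus", y = "prior density") +
    theme_minimal()
}

#' @rdname fitmax-autoplot
#' @export
autoplot.fm_response <- function(object, ...) {
  ggplot(object, aes(x = .data$s, y = .data$h)) +
    geom_line(color = "darkorange") +
    labs(x = "stimulus", y = "response h(s)",
         title = sprintf("escort response, gamma = %.3g", attr(object, "gamma"))) +
    theme_minimal()
}

#' @rdname fitmax-autoplot
#' @export
autoplot.fm_allocation <- function(object, ...) {
  ggplot(object, aes(x = .data$s, y = .data$f_tilde)) +
    geom_line(color = "firebrick") +
    labs(x = "stimulus", y = "normalized allocation",
         title = sprintf("Fisher allocation (k = %.3g)", attr(object, "k"))) +
    theme_minimal()
}

#' @rdname fitmax-autoplot
#' @export
autoplot.fm_fisher_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$angle, y = .data$J)) +
    geom_line(color = "darkgreen") +
    labs(x = "diagonality (deg)", y = "Fisher information") +
    theme_minimal()
}

#' Per-bin estimation variance before and after training
#'
#' @param summaries Output of [bin_summaries()].
#' @return A ggplot object.
#' @export
plot_bin_variance <- function(summaries) {
  long <- tidyr::pivot_longer(summaries, c("var_before", "var_after"),
                              names_to = "phase", values_to = "variance")
  ggplot(long, aes(x = .data$bin, y = .data$variance,
                   group = .data$phase, color = .data$phase)) +
    geom_point(stat = "summary", fun = mean) +
    geom_line(stat = "summary", fun = mean) +
    facet_wrap(~location) +
    labs(x = "diagonality bin", y = "estimation variance (deg^2)") +
    theme_minimal()
}

#' Posterior densities of a group-level parameter
#'
#' @param fit An `fm_fit`.
#' @param parameter Parameter name.
#' @return A ggplot object.
#' @export
plot_posterior <- function(fit, parameter = "q") {
  d <- fit$draws
  d <- d[d$parameter == parameter & d$level == "group_mean", ]
  ggplot(d, aes(x = .data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    labs(x = sprintf("group-level %s", parameter), y = "posterior density") +
    theme_minimal()
}
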