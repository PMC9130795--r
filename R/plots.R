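#' Distribution of dyadic sociality index values
#'
#' Histogram of DSI values per party-year on a log-ish scale (zeros kept in a
#' separate first bin), with the party average (1 by construction) marked.
#'
#' @param dsi output of [compute_dsi()].
#' @return a ggplot object.
#' @export
plot_dsi_distribution <- function(dsi) {
  ggplot2::ggplot(dsi, ggplot2::aes(x = .data$dsi)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "firebrick") +
    ggplot2::scale_x_sqrt() +
    ggplot2::facet_grid(party ~ year) +
    ggplot2::labs(x = "dyadic composite sociality index",
                  y = "number of dyads") +
    ggplot2::theme_minimal()
}

#' Effect plot for a fitted pipeline model
#'
#' Observed responses against the (transformed) predictor of interest, with
#' the fixed-effects fitted curve and, when a bootstrap was run, the
#' percentile confidence band (other predictors at their average).
#'
#' @param object a `bbn_glmm` from [fit_study_models()] (needs the
#'   `effect_term` tag) or any [fit_glmm()] fit with `term` supplied.
#' @param term predictor column to display (defaults to the tagged effect
#'   term).
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bbn_glmm <- function(object, term = object$effect_term, ...) {
  if (is.null(term)) abort("autoplot: no effect term tagged or supplied")
  object$effect_term <- term
  fd <- effect_plot_data(object)
  resp <- all.vars(object$formula)[1]
  obs <- tibble(x = object$data[[term]], y = object$data[[resp]])
  if (object$family == "poisson_log" && !is.null(object$offset_col)) {
    obs$y <- obs$y / object$data[[object$offset_col]]
  }
  p <- ggplot2::ggplot(obs, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::labs(x = term, y = resp) +
    ggplot2::theme_minimal()
  if (!is.null(fd)) {
    if (!all(is.na(fd$conf_low))) {
      p <- p + ggplot2::geom_ribbon(
        data = fd, ggplot2::aes(x = .data$x, ymin = .data$conf_low,
                                ymax = .data$conf_high),
        inherit.aes = FALSE, alpha = 0.2)
    }
    p <- p + ggplot2::geom_line(
      data = fd, ggplot2::aes(x = .data$x, y = .data$fitted),
      inherit.aes = FALSE, linewidth = 0.8, colour = "steelblue")
  }
  p
}
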