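# Diagnostic figures. Each major result type has an autoplot() method so a
# pipeline run can be inspected with a one-liner.

#' Plot a rupture-force distribution
#'
#' @param object A [rupture_density()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rupture_density
#' @export
autoplot.rupture_density <- function(object, ...) {
  ggplot2::ggplot(object$density, ggplot2::aes(x = .data$force,
                                               y = .data$density)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = object$mode, linetype = "dashed") +
    ggplot2::labs(x = "Force (pN)", y = "Density (1/pN)",
                  title = sprintf("Rupture-force distribution (mode %.1f pN)",
                                  object$mode),
                  subtitle = sprintf("Survival past ramp: %.1f%%",
                                     100 * object$survival)) +
    ggplot2::theme_minimal()
}

#' Plot a Dudko-Szabo fit over the rupture-force histogram
#'
#' @param object A `ds_fit` from [fit_ds()].
#' @param bin_width Histogram bin width, pN.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ds_fit
#' @export
autoplot.ds_fit <- function(object, bin_width = 1, ...) {
  rd <- rupture_density(object$mixture, object$schedule, kBT = object$kBT)
  unc <- object$data[!object$data$censored, ]
  ggplot2::ggplot(unc, ggplot2::aes(x = .data$force)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = bin_width, fill = "grey80",
                            colour = "grey40") +
    ggplot2::geom_line(data = rd$density,
                       ggplot2::aes(x = .data$force, y = .data$density),
                       colour = "firebrick", linewidth = 0.9) +
    ggplot2::labs(x = "Rupture force (pN)", y = "Density (1/pN)",
                  title = "Dudko-Szabo fit") +
    ggplot2::theme_minimal()
}

#' Plot a fixed-component mixture decomposition
#'
#' @param object A `fret_mixture_fit` from [decompose_mixture()].
#' @param summaries The molecule summaries that were decomposed (optional;
#'   when given, their histogram is drawn behind the component curves).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fret_mixture_fit
#' @export
autoplot.fret_mixture_fit <- function(object, summaries = NULL, ...) {
  grid <- seq(0, 1.2, by = 0.002)
  curves <- purrr::map_dfr(seq_len(nrow(object$components)), function(k) {
    tibble::tibble(
      label = object$components$label[k],
      E = grid,
      density = object$weights[k] *
        dnorm(grid, object$components$center[k], object$components$sigma[k])
    )
  })
  p <- ggplot2::ggplot()
  if (!is.null(summaries)) {
    p <- p + ggplot2::geom_histogram(
      data = summaries,
      ggplot2::aes(x = .data$E_mean, y = ggplot2::after_stat(density)),
      binwidth = 0.02, fill = "grey85", colour = "grey60")
  }
  p +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(x = .data$E, y = .data$density,
                                    colour = .data$label),
                       linewidth = 0.8) +
    ggplot2::labs(x = "FRET efficiency E", y = "Density",
                  colour = "Subpopulation") +
    ggplot2::theme_minimal()
}

#' Plot ensemble efficiency-versus-force curves per unfolding class
#'
#' @param binned Output of [mean_E_vs_force()].
#' @return A ggplot.
#' @export
plot_E_vs_force <- function(binned) {
  ggplot2::ggplot(binned, ggplot2::aes(x = .data$force_bin, y = .data$mean_E,
                                       colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_E - .data$se, ymax = .data$mean_E + .data$se),
      size = 0.2) +
    ggplot2::labs(x = "Force (pN)", y = "Mean FRET efficiency",
                  colour = "Class") +
    ggplot2::theme_minimal()
}

#' Plot a loading schedule
#'
#' @param object A [loading_schedule()].
#' @param ... Unused.
#' @return A ggplot of force versus time.
#' @method autoplot loading_schedule
#' @export
autoplot.loading_schedule <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$t_s,
                                            y = .data$force_pN)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Time (s)", y = "Force (pN)",
                  title = sprintf("Loading schedule: %.2g -> %.3g pN in %.2f s",
                                  object$F_min, object$F_max,
                                  object$duration)) +
    ggplot2::theme_minimal()
}
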