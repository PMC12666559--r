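#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a phase-fraction time course
#'
#' Stacked-area chart of the per-frame G1/S/G2M percentage distribution.
#'
#' @param object A `fucci_fractions` tibble from
#'   [phase_fraction_timecourse()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fucci_fractions <- function(object, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$pct))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h, y = .data$pct,
                                  fill = .data$phase)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = "Time after stimulation (h)", y = "Cells in phase (%)",
                  fill = "Phase") +
    ggplot2::theme_minimal()
}

#' Plot a transition-coupling fit
#'
#' Scatter of per-cell (G1/S, M/G1) transition times with the fitted OLS
#' line; slope, intercept and Pearson r are shown in the subtitle.
#'
#' @param object A `transition_fit` from [transition_regression()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transition_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$t_g1s, y = .data$t_mg1)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "G1/S transition time (h)", y = "M/G1 transition time (h)",
      subtitle = sprintf("s = %.2f, i = %.1f h, r = %.2f, n = %d",
                         object$slope, object$intercept, object$r, object$n)) +
    ggplot2::theme_minimal()
}

#' Histograms of cell-cycle transition times
#'
#' One panel per transition (G1/S, S/G2, M/G1) over complete cells, with
#' the cohort mean marked.
#'
#' @param timings Per-cell timing tibble from [call_cycle_timings()].
#' @param binwidth Histogram bin width in hours (default 2).
#' @return A ggplot object.
#' @export
plot_transition_histograms <- function(timings, binwidth = 2) {
  d <- timings |>
    dplyr::filter(.data$complete) |>
    dplyr::select("t_g1s", "t_sg2", "t_mg1") |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "transition",
                        values_to = "time_h") |>
    dplyr::mutate(transition = factor(.data$transition,
                                      levels = c("t_g1s", "t_sg2", "t_mg1"),
                                      labels = c("G1/S", "S/G2", "M/G1")))
  means <- d |>
    dplyr::group_by(.data$transition) |>
    dplyr::summarise(mean = mean(.data$time_h), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey60",
                            colour = "white") +
    ggplot2::geom_vline(data = means,
                        ggplot2::aes(xintercept = .data$mean),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~transition, ncol = 1) +
    ggplot2::labs(x = "Time after stimulation (h)", y = "Cells") +
    ggplot2::theme_minimal()
}

#' Plot a p-c-Myc / cyclin D1 ratio profile
#'
#' Per-cell ratios over DAPI intensity with the per-bin modal ratio
#' ("vertex") overlaid.
#'
#' @param object A `ratio_profile` from [myc_cyclin_ratio_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ratio_profile <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = .data$dapi, y = .data$ratio)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_point(data = object$vertices,
                        ggplot2::aes(x = .data$dapi_mid, y = .data$vertex),
                        colour = "firebrick", shape = 21, size = 3,
                        stroke = 1.2, fill = NA) +
    ggplot2::labs(x = "DAPI intensity (a.u.)",
                  y = "p-c-Myc / cyclin D1 ratio") +
    ggplot2::theme_minimal()
}
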