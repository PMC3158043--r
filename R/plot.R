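#' Heat map of a correlation surface
#'
#' Population response as a function of vertical position and preferred
#' disparity; undefined (edge-flagged) entries are omitted.
#'
#' @param object A [correlation_surface()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.correlation_surface <- function(object, ...) {
  as_tibble(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$dx, .data$y,
                                 fill = .data$correlation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                  high = "#a50026", limits = c(-1, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "preferred disparity (arcmin)",
                  y = "vertical position (arcmin)", fill = "C") +
    ggplot2::theme_minimal()
}

#' Psychometric curves of a simulated experiment
#'
#' Percent correct versus disparity amplitude, one panel per frequency,
#' colour by waveform, with 95% Wilson confidence intervals.
#'
#' @param object A [run_experiment()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stereo_experiment <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$amplitude, .data$percent_correct,
                               colour = .data$waveform,
                               shape = .data$waveform)) +
    ggplot2::geom_hline(yintercept = 50, linetype = 3, colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.05) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~frequency, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "disparity amplitude (arcmin)", y = "percent correct") +
    ggplot2::theme_minimal()
}

#' Upper depth limit versus frequency (log-log)
#'
#' @param object An [upper_depth_limit()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.depth_limit <- function(object, ...) {
  d <- dplyr::filter(object, !is.na(.data$limit))
  ggplot2::ggplot(d, ggplot2::aes(.data$frequency, .data$limit,
                                  colour = .data$waveform,
                                  shape = .data$censored)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(data = dplyr::filter(d, !.data$censored),
                         method = "lm", se = FALSE, linewidth = 0.4,
                         formula = y ~ x) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "corrugation frequency (cpd)",
                  y = "upper depth limit (arcmin)") +
    ggplot2::theme_minimal()
}

#' Side-by-side view of a stereo pair
#'
#' @param object A [stereo_pair()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stereo_pair <- function(object, ...) {
  one <- function(m, eye) tibble::tibble(
    x = rep((seq_len(ncol(m)) - 0.5) * object$pitch, each = nrow(m)),
    y = rep((seq_len(nrow(m)) - 0.5) * object$pitch, times = ncol(m)),
    luminance = as.numeric(m), eye = eye)
  dplyr::bind_rows(one(object$left, "left"), one(object$right, "right")) |>
    ggplot2::ggplot(ggplot2::aes(.data$x, .data$y, fill = .data$luminance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() + ggplot2::coord_equal() +
    ggplot2::facet_wrap(~eye) +
    ggplot2::labs(x = "x (arcmin)", y = "y (arcmin)") +
    ggplot2::theme_minimal()
}

#' @describeIn run_experiment the result is already tidy; returned as a
#'   plain tibble.
#' @param x A `stereo_experiment`.
#' @param ... Unused.
#' @export
tidy.stereo_experiment <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @describeIn run_experiment one-row summary of the simulated experiment.
#' @export
glance.stereo_experiment <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x), n_trials = sum(x$n_trials),
                 mean_percent_correct = mean(x$percent_correct),
                 seed = attr(x, "seed"))
}
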