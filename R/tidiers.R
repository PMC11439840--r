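# broom-style accessors and diagnostic plots.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a gaze_stat result
#'
#' Returns the test results as a plain tibble with one row per test or
#' effect.
#'
#' @param x A `gaze_stat` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy gaze_stat
#' @export
tidy.gaze_stat <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "gaze_stat")
  out
}

#' @rdname tidy.gaze_stat
#' @method glance gaze_stat
#' @export
glance.gaze_stat <- function(x, ...) {
  tibble::tibble(n_tests = nrow(x),
                 min_p = min(x$p_value, na.rm = TRUE),
                 any_corrected = any(x$correction != "none"))
}

#' Gaze trace diagnostic plot
#'
#' Plots one trial's horizontal/vertical gaze position over time with
#' detected (or ground-truth) saccade intervals shaded.
#'
#' @param samples Samples tibble of one trial.
#' @param events Optional events tibble of the same trial.
#' @return A ggplot object.
#' @export
plot_gaze_trace <- function(samples, events = NULL) {
  long <- tidyr::pivot_longer(samples, c("x_px", "y_px"),
                              names_to = "axis", values_to = "px")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t_ms, y = .data$px,
                                          colour = .data$axis)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "time (ms)", y = "gaze position (px)") +
    ggplot2::theme_minimal()
  if (!is.null(events)) {
    sac <- events[events$kind == "saccade", , drop = FALSE]
    if (nrow(sac) > 0) {
      p <- p + ggplot2::geom_rect(
        data = sac,
        ggplot2::aes(xmin = .data$onset_ms, xmax = .data$offset_ms),
        ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "grey40",
        inherit.aes = FALSE)
    }
  }
  p
}

#' Main-sequence diagnostic plot
#'
#' Peak velocity against amplitude for detected saccades, with the
#' parametric main-sequence curve of the simulator overlaid.
#'
#' @param events Events tibble.
#' @param params A [gaze_sim_params()] for the reference curve, or `NULL`.
#' @return A ggplot object.
#' @export
plot_main_sequence <- function(events, params = gaze_sim_params()) {
  sac <- events[events$kind == "saccade" & !is.na(events$amplitude_deg), ,
                drop = FALSE]
  p <- ggplot2::ggplot(sac, ggplot2::aes(x = .data$amplitude_deg,
                                         y = .data$peak_vel)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::labs(x = "amplitude (deg)", y = "peak velocity (deg/s)") +
    ggplot2::theme_minimal()
  if (!is.null(params)) {
    grid <- tibble::tibble(amplitude_deg = seq(0.5, max(2, sac$amplitude_deg),
                                               length.out = 100))
    grid$peak_vel <- mainseq_peak_velocity(grid$amplitude_deg, params)
    p <- p + ggplot2::geom_line(data = grid, colour = "red")
  }
  p
}

#' Sampling-summary bar plot
#'
#' Participant-mean fixation-count and dwell-time proportions per ROI
#' class.
#'
#' @param overall The `overall` tibble from [sampling_summary()].
#' @return A ggplot object.
#' @export
plot_sampling_summary <- function(overall) {
  long <- tidyr::pivot_longer(overall, c("count_pct", "dwell_pct"),
                              names_to = "measure", values_to = "pct")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$roi_class, y = .data$pct)) +
    ggplot2::stat_summary(fun = mean, geom = "col",
                          fill = "steelblue", na.rm = TRUE) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4, na.rm = TRUE) +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = NULL, y = "%") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
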