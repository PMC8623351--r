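#' Plot a rating-light matrix
#'
#' Renders the color-coded rating grid: one facet per muscle, electrode
#' position against stimulation amplitude, each cell colored gray (no
#' response), green (reflex), yellow (presumed M-wave), or red (invalid).
#' In the details variant the point size encodes the first-response
#' peak-to-peak amplitude, mirroring the rating-details view.
#'
#' @param object A `"tscs_rating"` tibble from [tscs_rate()].
#' @param details If `TRUE`, scale point size by `amp1_uV`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tscs_rating <- function(object, details = FALSE, ...) {
  pal <- c(no_response = "grey70", reflex = "#2e9e4f",
           m_wave = "#e8c531", invalid = "#d03c3c")
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data$amplitude_mA, y = factor(.data$electrode_position)))
  if (details) {
    p <- p + ggplot2::geom_point(ggplot2::aes(
      color = .data$label,
      size = ifelse(is.na(.data$amp1_uV), 0, .data$amp1_uV))) +
      ggplot2::scale_size_area("amp1 [µV]", max_size = 6)
  } else {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$label), size = 3)
  }
  p +
    ggplot2::facet_wrap(~muscle) +
    ggplot2::scale_color_manual(values = pal, name = "rating") +
    ggplot2::labs(x = "stimulation amplitude [mA]",
                  y = "electrode position (caudal → rostral)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.tscs_rating
#' @param rating A `"tscs_rating"` tibble.
#' @export
plot_rating_matrix <- function(rating, details = FALSE) {
  autoplot.tscs_rating(rating, details = details)
}

#' Plot averaged evoked responses
#'
#' Overlays the averaged EMG responses of one electrode position across
#' stimulation amplitudes, one facet per muscle, with the paired-pulse
#' measurement windows shaded. Useful for visually confirming reflex
#' recruitment and second-response suppression.
#'
#' @param responses Averaged-response tibble from [tscs_average_responses()].
#' @param electrode_position Electrode position to display.
#' @param cfg A [tscs_protocol()] configuration.
#' @return A ggplot object.
#' @export
plot_responses <- function(responses, electrode_position,
                           cfg = tscs_protocol()) {
  pos <- electrode_position
  sel <- responses |>
    filter(.data$electrode_position == pos, .data$status == "averaged")
  if (nrow(sel) == 0) abort("no averaged responses at that electrode position")
  long <- sel |>
    mutate(trace = map(.data$mean_series, function(s) {
      tibble(t_ms = cfg$average_window_ms[1] +
               (seq_along(s) - 1L) * 1000 / cfg$fs_hz, uV = s)
    })) |>
    select("muscle", "amplitude_mA", "trace") |>
    tidyr::unnest("trace")
  win1 <- cfg$amp_window_ms
  win2 <- cfg$amp_window_ms + cfg$ipi_ms
  ggplot2::ggplot(long, ggplot2::aes(.data$t_ms, .data$uV,
                                     color = factor(.data$amplitude_mA))) +
    ggplot2::annotate("rect", xmin = win1[1], xmax = win1[2], ymin = -Inf,
                      ymax = Inf, alpha = 0.08) +
    ggplot2::annotate("rect", xmin = win2[1], xmax = win2[2], ymin = -Inf,
                      ymax = Inf, alpha = 0.08) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~muscle, scales = "free_y") +
    ggplot2::labs(x = "time after first stimulus [ms]", y = "EMG [µV]",
                  color = "I [mA]",
                  title = paste("Averaged responses, electrode position", pos)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
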