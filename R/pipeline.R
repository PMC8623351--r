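#' Run the full calibration pipeline on a session
#'
#' End-to-end calibration: synchronize every sweep to its first stimulation
#' artifact, pre-filter (offset removal, artifact blanking, zero-phase
#' band-stop and low-pass), profile the muscle-specific base noise level,
#' gate repetitions by similarity and average them, rate every (muscle,
#' electrode, amplitude) cell, and derive the therapy recommendation with
#' both the ranking and the cost-function approach.
#'
#' @param session A session tibble ([read_tscs_session()],
#'   [tscs_simulate_session()]) or a path to a session CSV.
#' @param cfg A [tscs_protocol()] configuration.
#' @return An object of class `"tscs_calibration"`: a list with `rating`
#'   (tibble), `recommendation` (`"tscs_recommendation"`), `noise` (tibble),
#'   `responses` (averaged-response tibble), `dispositions` (per-sweep status
#'   counts), `invalid_cell_ratio`, and `cfg`.
#' @examples
#' cfg <- tscs_protocol(electrode_positions = 1:2,
#'                      amplitudes_mA = seq(5, 30, by = 5))
#' sess <- tscs_simulate_session(tscs_sim_truth(cfg), cfg, seed = 7)
#' cal <- tscs_calibrate(sess, cfg)
#' cal$recommendation
#' @export
tscs_calibrate <- function(session, cfg = tscs_protocol()) {
  if (is.character(session)) session <- read_tscs_session(session, cfg)
  synced <- tscs_synchronize(session, cfg)
  filtered <- tscs_prefilter(synced, cfg)
  noise <- tscs_noise_profile(filtered, cfg)
  responses <- tscs_average_responses(filtered, noise, cfg)
  rating <- tscs_rate(responses, noise, cfg)
  recommendation <- tscs_recommend(rating, cfg)

  dispositions <- synced |>
    distinct(.data$electrode_position, .data$amplitude_mA, .data$repetition,
             .data$status) |>
    dplyr::count(.data$status, name = "n_sweeps")

  out <- list(rating = rating,
              recommendation = recommendation,
              noise = noise,
              responses = responses,
              dispositions = dispositions,
              invalid_cell_ratio = mean(rating$label == "invalid"),
              cfg = cfg)
  class(out) <- "tscs_calibration"
  out
}

#' @export
print.tscs_calibration <- function(x, ...) {
  cat("<tscs_calibration>\n")
  cat(sprintf("  %d rated cells (%d muscles x %d electrode/amplitude pairs)\n",
              nrow(x$rating), length(unique(x$rating$muscle)),
              nrow(distinct(x$rating, .data$electrode_position,
                            .data$amplitude_mA))))
  counts <- table(x$rating$label)
  cat("  labels:", paste(sprintf("%s=%d", names(counts), counts),
                         collapse = ", "), "\n")
  cat(sprintf("  invalid cell ratio: %.1f%%\n", 100 * x$invalid_cell_ratio))
  print(x$recommendation)
  invisible(x)
}

#' Tidy / summarize a calibration
#'
#' `tidy()` returns the per-cell rating table; `glance()` a one-row summary
#' of the session (label counts, invalid ratio, recommendation).
#'
#' @param x A `"tscs_calibration"` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tscs_calibration <- function(x, ...) as_tibble(x$rating)

#' @rdname tidy.tscs_calibration
#' @export
glance.tscs_calibration <- function(x, ...) {
  lab <- x$rating$label
  dplyr::bind_cols(
    tibble(n_cells = length(lab),
           n_reflex = sum(lab == "reflex"),
           n_m_wave = sum(lab == "m_wave"),
           n_no_response = sum(lab == "no_response"),
           n_invalid = sum(lab == "invalid"),
           invalid_cell_ratio = x$invalid_cell_ratio),
    glance(x$recommendation))
}

#' Write the report files of a calibration
#'
#' Convenience wrapper around [write_tscs_report()] embedding the noise
#' profile and sweep dispositions of a [tscs_calibrate()] result.
#'
#' @param cal A `"tscs_calibration"` object.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_tscs_calibration <- function(cal, dir) {
  stopifnot(inherits(cal, "tscs_calibration"))
  write_tscs_report(cal$rating, cal$recommendation, dir,
                    noise = cal$noise,
                    dispositions = df_to_records(cal$dispositions))
}
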