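#' Peak-to-peak amplitude of an averaged evoked response
#'
#' Measures `max - min` of the averaged series within the response window
#' (default 10-45 ms) after the first or the second stimulus of the double
#' pulse; the second window is the first shifted by the inter-pulse interval
#' (default 60-95 ms). Both windows lie clear of the blanked artifact
#' intervals by configuration-time assertion.
#'
#' @param mean_series Averaged series on the response time axis (default -1
#'   to 200 ms).
#' @param which `"first"` or `"second"` stimulus.
#' @param cfg A [tscs_protocol()] configuration.
#' @return Peak-to-peak amplitude in microvolts.
#' @examples
#' cfg <- tscs_protocol()
#' s <- numeric(202); s[16] <- 300; s[20] <- -100  # t = 14 ms lobe
#' tscs_peak_to_peak(s, "first", cfg)
#' @export
tscs_peak_to_peak <- function(mean_series, which = c("first", "second"),
                              cfg = tscs_protocol()) {
  which <- match.arg(which)
  win <- cfg$amp_window_ms + if (which == "second") cfg$ipi_ms else 0
  idx <- window_indices(win, cfg$fs_hz, cfg$average_window_ms[1],
                        length(mean_series))
  if (length(idx) < diff(ms_to_index(win, cfg$fs_hz, win[1])) + 1L)
    abort("peak-to-peak window extends beyond the averaged series")
  max(mean_series[idx]) - min(mean_series[idx])
}

#' Paired-pulse suppression ratio
#'
#' `1 - amp2/amp1`, clipped to `[0, 1]`. One means complete suppression of
#' the response to the second stimulus — the post-activation depression
#' characteristic of posterior root-muscle reflexes; zero means two responses
#' of equal size, as produced by direct motor responses (M-waves), which show
#' no paired-pulse depression. With `amp1 = 0` there is no response whose
#' suppression could be assessed; the ratio is defined as 0.
#'
#' @param amp1,amp2 Peak-to-peak amplitudes (microvolts) of the responses to
#'   the first and second stimulus.
#' @return Suppression ratio in `[0, 1]`.
#' @examples
#' tscs_suppression(400, 0)    # complete suppression
#' tscs_suppression(400, 400)  # no suppression
#' @export
tscs_suppression <- function(amp1, amp2) {
  stopifnot(is.numeric(amp1), is.numeric(amp2))
  ifelse(amp1 <= 0, 0, pmin(1, pmax(0, 1 - amp2 / amp1)))
}

#' Classify one evoked response into the four-color rating system
#'
#' Applies the rating rules: a cell is `no_response` (gray) when `amp1` does
#' not exceed both gates (`noise_sd_factor` times the muscle's base noise
#' level, and `min_amp_uV`); `reflex` (green) when it exceeds both gates and
#' the suppression ratio strictly exceeds `suppression_threshold`; `m_wave`
#' (yellow) when it exceeds both gates with suppression at or below the
#' threshold; and `invalid` (red) when no similar repetitions were obtained.
#' The rules are exhaustive and mutually exclusive.
#'
#' @param amp1 Peak-to-peak amplitude after the first stimulus, microvolts
#'   (ignored when `valid = FALSE`).
#' @param sup Suppression ratio in `[0, 1]`.
#' @param noise_uV Muscle-specific base noise level, microvolts.
#' @param valid `FALSE` for cells that failed the similarity gate.
#' @param cfg A [tscs_protocol()] configuration.
#' @return One of `"no_response"`, `"reflex"`, `"m_wave"`, `"invalid"`.
#' @examples
#' tscs_classify(100, 0.8, 5)  # reflex
#' tscs_classify(100, 0.5, 5)  # m_wave
#' tscs_classify(40, 0.9, 2)   # no_response (50 uV gate)
#' @export
tscs_classify <- function(amp1, sup, noise_uV, valid = TRUE,
                          cfg = tscs_protocol()) {
  if (!valid) return("invalid")
  responded <- amp1 > cfg$noise_sd_factor * noise_uV & amp1 > cfg$min_amp_uV
  if (!responded) return("no_response")
  if (sup > cfg$suppression_threshold) "reflex" else "m_wave"
}

rating_colors <- c(no_response = "gray", reflex = "green",
                   m_wave = "yellow", invalid = "red")

#' Build the rating matrix of a session
#'
#' Extracts peak-to-peak amplitudes and the suppression ratio from every
#' averaged response and classifies each (muscle, electrode position,
#' amplitude) cell with [tscs_classify()]. Baseline cells (no detectable
#' stimulus artifact, typical at low amplitudes) are rated `no_response`
#' with zero amplitudes. Invalid cells carry no features.
#'
#' @param responses Averaged-response tibble from [tscs_average_responses()].
#' @param noise Noise profile tibble from [tscs_noise_profile()].
#' @param cfg A [tscs_protocol()] configuration.
#' @return A tibble of class `"tscs_rating"` with one row per cell: `muscle`,
#'   `electrode_position`, `amplitude_mA`, `label`, `color`, `amp1_uV`,
#'   `amp2_uV`, `suppression`, `n_averaged`.
#' @export
tscs_rate <- function(responses, noise, cfg = tscs_protocol()) {
  noise_lookup <- setNames(noise$noise_uV, noise$muscle)
  rate_row <- function(muscle, status, mean_series, n_averaged) {
    if (identical(status, "invalid")) {
      return(tibble(label = "invalid", amp1_uV = NA_real_, amp2_uV = NA_real_,
                    suppression = NA_real_))
    }
    if (identical(status, "baseline")) {
      return(tibble(label = "no_response", amp1_uV = 0, amp2_uV = 0,
                    suppression = 0))
    }
    a1 <- tscs_peak_to_peak(mean_series, "first", cfg)
    a2 <- tscs_peak_to_peak(mean_series, "second", cfg)
    sup <- tscs_suppression(a1, a2)
    tibble(label = tscs_classify(a1, sup, noise_lookup[[muscle]], TRUE, cfg),
           amp1_uV = a1, amp2_uV = a2, suppression = sup)
  }
  rated <- responses |>
    mutate(rated = pmap(list(.data$muscle, .data$status, .data$mean_series,
                             .data$n_averaged), rate_row)) |>
    select("muscle", "electrode_position", "amplitude_mA", "n_averaged",
           "rated") |>
    tidyr::unnest("rated") |>
    mutate(color = unname(rating_colors[.data$label])) |>
    select("muscle", "electrode_position", "amplitude_mA", "label", "color",
           "amp1_uV", "amp2_uV", "suppression", "n_averaged") |>
    arrange(.data$electrode_position, .data$amplitude_mA, .data$muscle)
  class(rated) <- c("tscs_rating", class(rated))
  rated
}
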