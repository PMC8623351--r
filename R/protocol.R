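#' Calibration protocol and analysis configuration
#'
#' Builds the configuration object consumed by every pipeline stage: the
#' stimulation protocol (electrode positions, amplitude ramp, repetitions,
#' inter-pulse interval, sampling rate, muscle channels) and the analysis
#' parameters (artifact-detection windows, filter design, similarity gate,
#' rating thresholds, therapy rule). Defaults reproduce the published
#' calibration procedure: four rostrocaudal electrode positions, a 5-75 mA
#' ramp in 5 mA steps, three paired pulses (50 ms inter-pulse interval) per
#' amplitude, and EMG at 1 kHz from bilateral quadriceps (LQ, RQ) and triceps
#' surae (LTS, RTS).
#'
#' @param electrode_positions Integer vector of electrode positions, ordered
#'   caudal to rostral.
#' @param amplitudes_mA Strictly increasing arithmetic amplitude grid in mA.
#' @param repetitions Number of paired-pulse repetitions per amplitude.
#' @param ipi_ms Inter-pulse interval of the double stimulus in ms; must be a
#'   whole number of samples at `fs_hz`.
#' @param fs_hz EMG sampling rate in Hz.
#' @param muscles Ordered muscle channel labels.
#' @param limb_grouping Named character vector mapping each muscle to its
#'   sensor group (one wireless sensor per limb).
#' @param detection_channels Muscles used for stimulation-artifact detection.
#' @param search_window Sample-index interval (1-based, raw sweep frame) in
#'   which the first artifact is sought.
#' @param tail_window Sample-index interval of the raw sweep used to estimate
#'   the dispersion of the double-differentiated signal.
#' @param detection_sd_factor Artifact threshold as a multiple of that
#'   dispersion.
#' @param crop_window_ms Time range retained around the first stimulus, ms.
#' @param blank_windows_ms List of closed ms intervals blanked around the two
#'   stimulation artifacts.
#' @param bandstop_hz Passband edges of the second-order Butterworth band-stop
#'   (notch) filter, Hz.
#' @param lowpass_hz Cutoff of the first-order Butterworth low-pass filter, Hz.
#' @param noise_window_ms Late time window pooled across sweeps for the
#'   muscle-specific base noise level, ms.
#' @param similarity_windows_ms Windows over which repetition similarity RMSE
#'   is computed, ms.
#' @param similarity_factor Repetitions are similar when their RMSE is below
#'   `similarity_factor` times the muscle's base noise level.
#' @param average_window_ms Time range of the averaged response, ms.
#' @param amp_window_ms Peak-to-peak measurement window after each stimulus,
#'   ms.
#' @param min_amp_uV Absolute response gate in microvolts.
#' @param noise_sd_factor Response gate as a multiple of the base noise level.
#' @param suppression_threshold Suppression above which a response counts as a
#'   reflex.
#' @param min_green_muscles Minimal number of reflex-positive muscles for a
#'   candidate (electrode, amplitude) pair.
#' @param therapy_fraction Therapy amplitude as a fraction of the reflex
#'   threshold.
#' @param rounding `"grid"` floors the therapy amplitude to the amplitude
#'   grid; `"none"` keeps the exact value.
#'
#' @return A list with class `"tscs_protocol"`.
#' @examples
#' cfg <- tscs_protocol()
#' cfg$amplitudes_mA
#' @export
tscs_protocol <- function(electrode_positions = 1:4,
                          amplitudes_mA = seq(5, 75, by = 5),
                          repetitions = 3L,
                          ipi_ms = 50,
                          fs_hz = 1000,
                          muscles = c("LQ", "LTS", "RQ", "RTS"),
                          limb_grouping = c(LQ = "left", LTS = "left",
                                            RQ = "right", RTS = "right"),
                          detection_channels = c("LQ", "RQ"),
                          search_window = c(10L, 200L),
                          tail_window = c(300L, 600L),
                          detection_sd_factor = 3,
                          crop_window_ms = c(-30, 300),
                          blank_windows_ms = list(c(-2, 2), c(48, 52)),
                          bandstop_hz = c(43, 47),
                          lowpass_hz = 300,
                          noise_window_ms = c(100, 300),
                          similarity_windows_ms = list(c(5, 45), c(55, 95)),
                          similarity_factor = 16,
                          average_window_ms = c(-1, 200),
                          amp_window_ms = c(10, 45),
                          min_amp_uV = 50,
                          noise_sd_factor = 6,
                          suppression_threshold = 0.60,
                          min_green_muscles = 2L,
                          therapy_fraction = 0.9,
                          rounding = c("grid", "none")) {
  cfg <- list(
    electrode_positions = as.integer(electrode_positions),
    amplitudes_mA = as.numeric(amplitudes_mA),
    repetitions = as.integer(repetitions),
    ipi_ms = ipi_ms,
    fs_hz = fs_hz,
    muscles = as.character(muscles),
    limb_grouping = limb_grouping,
    detection_channels = as.character(detection_channels),
    search_window = as.integer(search_window),
    tail_window = as.integer(tail_window),
    detection_sd_factor = detection_sd_factor,
    crop_window_ms = as.numeric(crop_window_ms),
    blank_windows_ms = lapply(blank_windows_ms, as.numeric),
    bandstop_hz = as.numeric(bandstop_hz),
    lowpass_hz = lowpass_hz,
    noise_window_ms = as.numeric(noise_window_ms),
    similarity_windows_ms = lapply(similarity_windows_ms, as.numeric),
    similarity_factor = similarity_factor,
    average_window_ms = as.numeric(average_window_ms),
    amp_window_ms = as.numeric(amp_window_ms),
    min_amp_uV = min_amp_uV,
    noise_sd_factor = noise_sd_factor,
    suppression_threshold = suppression_threshold,
    min_green_muscles = as.integer(min_green_muscles),
    therapy_fraction = therapy_fraction,
    rounding = match.arg(rounding)
  )
  class(cfg) <- "tscs_protocol"
  validate_tscs_protocol(cfg)
}

#' Validate a protocol configuration
#'
#' Checks the structural invariants of a [tscs_protocol()] object: strictly
#' increasing constant-step amplitude grid, inter-pulse interval expressible
#' as a whole number of samples, every muscle assigned to exactly one sensor
#' group, low-pass cutoff below the Nyquist frequency, and peak-to-peak
#' windows that do not overlap the blanked artifact intervals.
#'
#' @param cfg A `"tscs_protocol"` object.
#' @return `cfg`, invisibly unchanged, or an error.
#' @export
validate_tscs_protocol <- function(cfg) {
  amps <- cfg$amplitudes_mA
  if (length(amps) < 1L || any(diff(amps) <= 0))
    abort("amplitude grid must be strictly increasing")
  if (length(amps) > 2L && length(unique(round(diff(amps), 9))) != 1L)
    abort("amplitude grid must have a constant step")
  ipi_samples <- cfg$ipi_ms * cfg$fs_hz / 1000
  if (abs(ipi_samples - round(ipi_samples)) > 1e-9)
    abort("inter-pulse interval must be a whole number of samples")
  if (!all(cfg$muscles %in% names(cfg$limb_grouping)))
    abort("every muscle must belong to exactly one sensor group")
  if (cfg$fs_hz <= 2 * cfg$lowpass_hz)
    abort("sampling rate must exceed twice the low-pass cutoff")
  if (!all(cfg$detection_channels %in% cfg$muscles))
    abort("detection channels must be among the configured muscles")
  # The measurement windows must stay clear of the blanked artifact intervals,
  # otherwise peak-to-peak amplitudes would silently include forced zeros.
  ipi <- cfg$ipi_ms
  amp_wins <- list(cfg$amp_window_ms, cfg$amp_window_ms + ipi)
  for (aw in amp_wins) {
    for (bw in cfg$blank_windows_ms) {
      if (aw[1] <= bw[2] && bw[1] <= aw[2])
        abort("peak-to-peak window overlaps a blanked artifact interval")
    }
  }
  invisible(cfg)
}

ipi_samples <- function(cfg) as.integer(round(cfg$ipi_ms * cfg$fs_hz / 1000))

# Number of samples in the aligned sweep (crop window, closed).
aligned_length <- function(cfg) {
  diff(ms_to_index(cfg$crop_window_ms, cfg$fs_hz, cfg$crop_window_ms[1])) + 1L
}

#' Read / write a protocol configuration as JSON
#'
#' @param path File path.
#' @param cfg A `"tscs_protocol"` object.
#' @return `read_tscs_protocol()` returns a `"tscs_protocol"`;
#'   `write_tscs_protocol()` returns `path` invisibly.
#' @export
read_tscs_protocol <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- formals(tscs_protocol)
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  if (!is.null(raw$limb_grouping))
    raw$limb_grouping <- unlist(raw$limb_grouping)
  if (!is.null(raw$blank_windows_ms) && is.matrix(raw$blank_windows_ms))
    raw$blank_windows_ms <- asplit(raw$blank_windows_ms, 1)
  if (!is.null(raw$similarity_windows_ms) && is.matrix(raw$similarity_windows_ms))
    raw$similarity_windows_ms <- asplit(raw$similarity_windows_ms, 1)
  do.call(tscs_protocol, raw)
}

#' @rdname read_tscs_protocol
#' @export
write_tscs_protocol <- function(cfg, path) {
  stopifnot(inherits(cfg, "tscs_protocol"))
  out <- unclass(cfg)
  out$limb_grouping <- as.list(out$limb_grouping)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.tscs_protocol <- function(x, ...) {
  cat("<tscs_protocol>\n")
  cat("  electrode positions:", paste(x$electrode_positions, collapse = ", "), "\n")
  cat(sprintf("  amplitude grid: %g..%g mA, step %g\n",
              min(x$amplitudes_mA), max(x$amplitudes_mA),
              if (length(x$amplitudes_mA) > 1) diff(x$amplitudes_mA)[1] else NA))
  cat(sprintf("  %d repetitions, inter-pulse interval %g ms, fs %g Hz\n",
              x$repetitions, x$ipi_ms, x$fs_hz))
  cat("  muscles:", paste(x$muscles, collapse = ", "), "\n")
  invisible(x)
}
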