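#' Offset removal, artifact blanking, and zero-phase filtering
#'
#' Pre-filters every aligned or baseline sweep channel of a synchronized
#' session: (1) the channel median is subtracted (offset correction); (2) for
#' aligned sweeps the closed intervals around the two stimulation artifacts
#' (default -2..2 ms and 48..52 ms) are blanked to zero; (3) a second-order
#' Butterworth band-stop (default 43-47 Hz) and a first-order Butterworth
#' low-pass (default 300 Hz) are applied non-causally, i.e. forward and
#' backward for zero net phase, so response latencies are not shifted;
#' (4) the blanked intervals are restored (set back to zero) so filter
#' ringing from the artifact edges cannot leak into the measurement windows.
#' Baseline sweeps carry no stimulus, so blanking is skipped for them.
#'
#' @param synced Synchronized session tibble from [tscs_synchronize()].
#' @param cfg A [tscs_protocol()] configuration.
#' @return The input tibble with `samples` replaced by filtered series
#'   (discarded sweeps keep `NULL` samples).
#' @export
tscs_prefilter <- function(synced, cfg = tscs_protocol()) {
  if (cfg$fs_hz <= 2 * cfg$lowpass_hz)
    abort("low-pass cutoff must lie below the Nyquist frequency")
  bs <- signal::butter(2, cfg$bandstop_hz / (cfg$fs_hz / 2), type = "stop")
  lp <- signal::butter(1, cfg$lowpass_hz / (cfg$fs_hz / 2), type = "low")
  synced |>
    mutate(samples = map2(.data$samples, .data$status, function(x, st) {
      if (is.null(x) || identical(st, "discarded")) return(NULL)
      prefilter_series(x, cfg, blank = identical(st, "aligned"),
                       bs = bs, lp = lp)
    }))
}

prefilter_series <- function(x, cfg, blank = TRUE, bs = NULL, lp = NULL) {
  if (is.null(bs)) bs <- signal::butter(2, cfg$bandstop_hz / (cfg$fs_hz / 2),
                                        type = "stop")
  if (is.null(lp)) lp <- signal::butter(1, cfg$lowpass_hz / (cfg$fs_hz / 2),
                                        type = "low")
  x <- x - median(x)
  blank_idx <- integer(0)
  if (blank) {
    blank_idx <- unlist(lapply(cfg$blank_windows_ms, window_indices,
                               fs_hz = cfg$fs_hz,
                               t_start_ms = cfg$crop_window_ms[1],
                               len = length(x)))
    x[blank_idx] <- 0
  }
  y <- filtfilt_reflect(bs, x)
  y <- filtfilt_reflect(lp, y)
  if (blank) y[blank_idx] <- 0
  y
}

# Forward-backward (zero-phase) filtering with odd-reflection edge padding
# of three filter orders, so startup transients decay in the extension
# rather than inside the sweep.
filtfilt_reflect <- function(filt, x) {
  n <- length(x)
  pad <- min(n - 1L, 3L * (max(length(filt$a), length(filt$b)) - 1L))
  xp <- if (pad > 0L) {
    c(2 * x[1] - x[(pad + 1L):2], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  } else x
  y <- rev(as.numeric(signal::filter(filt, xp)))
  y <- rev(as.numeric(signal::filter(filt, y)))
  y[(pad + 1L):(pad + n)]
}

#' Muscle-specific base noise level of a session
#'
#' For each muscle, the base noise level is the standard deviation of all
#' filtered EMG samples in the late window 100-300 ms pooled over every
#' retained (aligned or baseline) sweep of the session — a per-muscle,
#' per-session estimate of resting EMG dispersion against which evoked
#' responses are gated. For aligned sweeps the window is relative to the
#' first stimulus; for baseline sweeps (no stimulus time) the same positional
#' window of the extracted samples is used.
#'
#' @param filtered Filtered session tibble from [tscs_prefilter()].
#' @param cfg A [tscs_protocol()] configuration.
#' @return A tibble with columns `muscle` and `noise_uV`.
#' @export
tscs_noise_profile <- function(filtered, cfg = tscs_protocol()) {
  usable <- filter(filtered, .data$status %in% c("aligned", "baseline"))
  prof <- map(setNames(cfg$muscles, cfg$muscles), function(m) {
    rows <- filter(usable, .data$muscle == m)
    pooled <- unlist(map(rows$samples, function(x) {
      idx <- window_indices(cfg$noise_window_ms, cfg$fs_hz,
                            cfg$crop_window_ms[1], length(x))
      x[idx]
    }))
    if (length(pooled) < 2L)
      abort(paste0("no usable sweeps to profile noise for muscle ", m))
    sd(pooled)
  })
  tibble(muscle = names(prof), noise_uV = unname(unlist(prof)))
}

#' Similarity gate over the repetitions of one (muscle, electrode, amplitude)
#'
#' Evoked responses are only trusted when they replicate: the root mean
#' square error between each pair of repetitions is computed over the
#' response windows (default 5-45 ms plus 55-95 ms, excluding the blanked
#' artifacts), and a pair counts as similar when its RMSE is below
#' `similarity_factor` (default 16) times the muscle's base noise level. The
#' largest mutually similar subset is returned if it has at least two
#' members; otherwise the recording is invalid (movement-corrupted sweeps or
#' misdetected artifacts typically fail here). Subsets of equal size are
#' resolved in favor of the lowest repetition indices.
#'
#' @param reps List of filtered aligned series (one per repetition).
#' @param noise_uV Base noise level of the muscle, microvolts.
#' @param cfg A [tscs_protocol()] configuration.
#' @return A list with `keep` (integer indices into `reps`, empty if
#'   invalid) and `valid` (logical).
#' @export
tscs_similarity_gate <- function(reps, noise_uV, cfg = tscs_protocol()) {
  k <- length(reps)
  if (k < 2L) return(list(keep = integer(0), valid = FALSE,
                          reason = "insufficient repetitions"))
  len <- min(lengths(reps))
  idx <- unlist(lapply(cfg$similarity_windows_ms, window_indices,
                       fs_hz = cfg$fs_hz, t_start_ms = cfg$crop_window_ms[1],
                       len = len))
  similar <- matrix(TRUE, k, k)
  for (a in seq_len(k - 1L)) {
    for (b in seq.int(a + 1L, k)) {
      s <- rmse(reps[[a]][idx], reps[[b]][idx]) <
        cfg$similarity_factor * noise_uV
      similar[a, b] <- s
      similar[b, a] <- s
    }
  }
  # enumerate candidate subsets largest-first, lexicographic within a size;
  # at 3 repetitions this is at most 4 subsets
  for (size in seq.int(k, 2L)) {
    combs <- utils::combn(k, size, simplify = FALSE)
    for (sub in combs) {
      if (all(similar[sub, sub])) {
        return(list(keep = sub, valid = TRUE, reason = NA_character_))
      }
    }
  }
  list(keep = integer(0), valid = FALSE, reason = "no similar repetitions")
}

#' Average similar repetitions into mean evoked responses
#'
#' For each (muscle, electrode position, amplitude), the repetitions that
#' pass the similarity gate are cropped to the response window (default -1 to
#' 200 ms, 202 samples at 1 kHz) and averaged pointwise. Cells whose
#' repetitions are all baseline sweeps are marked `baseline` (no stimulus
#' artifact was detectable — rated as "no response" downstream); cells
#' without at least two usable repetitions, or failing the similarity gate,
#' are `invalid`.
#'
#' @param filtered Filtered session tibble from [tscs_prefilter()].
#' @param noise Noise profile tibble from [tscs_noise_profile()].
#' @param cfg A [tscs_protocol()] configuration.
#' @return A tibble with one row per (muscle, electrode_position,
#'   amplitude_mA): `status` (`averaged`, `baseline`, `invalid`),
#'   `n_averaged`, `kept_repetitions` (list), `reason`, and `mean_series`
#'   (list; the averaged series for `averaged` cells, `NULL` otherwise).
#' @export
tscs_average_responses <- function(filtered, noise, cfg = tscs_protocol()) {
  noise_lookup <- setNames(noise$noise_uV, noise$muscle)
  filtered |>
    group_by(.data$muscle, .data$electrode_position, .data$amplitude_mA) |>
    summarise(cell = list(average_cell(
      .data$samples, .data$status, .data$repetition,
      noise_lookup[[.data$muscle[1]]], cfg)), .groups = "drop") |>
    mutate(status = purrr::map_chr(.data$cell, "status"),
           n_averaged = map_int(.data$cell, "n_averaged"),
           kept_repetitions = map(.data$cell, "kept_repetitions"),
           reason = purrr::map_chr(.data$cell, "reason"),
           mean_series = map(.data$cell, "mean_series")) |>
    select(-"cell")
}

average_cell <- function(samples, status, repetition, noise_uV, cfg) {
  ord <- order(repetition)
  samples <- samples[ord]; status <- status[ord]; repetition <- repetition[ord]
  al <- which(status == "aligned")
  bl <- which(status == "baseline")
  if (length(al) >= 2L) {
    gate <- tscs_similarity_gate(samples[al], noise_uV, cfg)
    if (!gate$valid) {
      return(list(status = "invalid", n_averaged = 0L,
                  kept_repetitions = integer(0),
                  reason = gate$reason, mean_series = NULL))
    }
    keep <- al[gate$keep]
    idx <- window_indices(cfg$average_window_ms, cfg$fs_hz,
                          cfg$crop_window_ms[1],
                          min(lengths(samples[keep])))
    cropped <- lapply(samples[keep], function(x) x[idx])
    lens <- unique(lengths(cropped))
    if (length(lens) != 1L)
      abort("internal integrity error: mismatched series lengths in average")
    return(list(status = "averaged", n_averaged = length(keep),
                kept_repetitions = repetition[keep],
                reason = NA_character_,
                mean_series = Reduce(`+`, cropped) / length(cropped)))
  }
  if (length(bl) >= 2L) {
    return(list(status = "baseline", n_averaged = 0L,
                kept_repetitions = integer(0),
                reason = "baseline only", mean_series = NULL))
  }
  list(status = "invalid", n_averaged = 0L,
       kept_repetitions = integer(0),
       reason = "insufficient repetitions", mean_series = NULL)
}
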