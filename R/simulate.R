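#' Biphasic evoked-response waveform
#'
#' A Gaussian-windowed single-cycle sine — a compact biphasic wavelet that
#' mimics the shape of a compound muscle action potential. The wavelet starts
#' at `latency_ms` after the stimulus, spans roughly `width_ms`, and is
#' scaled so its peak-to-peak amplitude (measured on a dense internal grid)
#' equals `amplitude_uV`.
#'
#' @param t_ms Numeric vector of times (ms, relative to the stimulus) at
#'   which to evaluate the waveform.
#' @param latency_ms Response onset latency in ms; must lie in `[10, 40]` so
#'   the response falls inside the standard 10-45 ms measurement window.
#' @param amplitude_uV Requested peak-to-peak amplitude, microvolts.
#' @param width_ms Duration of the single cycle, ms.
#' @return Numeric vector of amplitudes at `t_ms`.
#' @examples
#' t <- seq(-1, 200, by = 1)
#' w <- tscs_response_waveform(t, latency_ms = 15, amplitude_uV = 400)
#' max(w) - min(w)
#' @export
tscs_response_waveform <- function(t_ms, latency_ms, amplitude_uV,
                                   width_ms = 8) {
  if (latency_ms < 10 || latency_ms > 40)
    abort("response latency must lie within [10, 40] ms")
  if (amplitude_uV == 0) return(numeric(length(t_ms)))
  unit <- function(t) {
    phase <- (t - latency_ms) / width_ms
    env <- exp(-((t - latency_ms - width_ms / 2) / (width_ms / 4))^2 / 2)
    sin(2 * pi * phase) * env
  }
  dense <- unit(seq(latency_ms - width_ms, latency_ms + 2 * width_ms,
                    by = 0.01))
  scale <- amplitude_uV / (max(dense) - min(dense))
  scale * unit(t_ms)
}

#' Sigmoid recruitment of response amplitude with stimulation amplitude
#'
#' Evoked-response amplitude grows sigmoidally with stimulation amplitude:
#' near zero well below the recruitment threshold, half-maximal at the
#' threshold (the sigmoid midpoint), and saturating at `max_amp_uV` above
#' it. The default slope (1.5 mA) makes the transition essentially complete
#' within two 5 mA grid steps, as seen in recruitment of posterior
#' root-muscle reflexes under incremental stimulation.
#'
#' @param amplitude_mA Stimulation amplitude(s), mA.
#' @param threshold_mA Recruitment threshold (sigmoid midpoint), mA.
#' @param max_amp_uV Saturation peak-to-peak amplitude, microvolts.
#' @param slope_mA Sigmoid slope parameter, mA.
#' @return Response peak-to-peak amplitude(s), microvolts.
#' @examples
#' tscs_recruitment(c(30, 40, 50), threshold_mA = 40, max_amp_uV = 400)
#' @export
tscs_recruitment <- function(amplitude_mA, threshold_mA, max_amp_uV,
                             slope_mA = 1.5) {
  stopifnot(threshold_mA > 0, max_amp_uV >= 0, slope_mA > 0)
  max_amp_uV / (1 + exp(-(amplitude_mA - threshold_mA) / slope_mA))
}

#' Ground truth for a simulated calibration session
#'
#' Defines, per (muscle, electrode position), the recruitment threshold,
#' response type, suppression level, latency, and maximal amplitude, plus
#' session-level noise and artifact parameters. The default truth emulates a
#' typical calibration: electrode 2 (overlying the target posterior roots)
#' recruits reflexes in all four muscles with triceps surae thresholds at
#' 40 mA and quadriceps at 45 mA; electrode 1 (caudal) recruits triceps
#' surae reflexes only; electrode 3 elicits quadriceps reflexes at higher
#' threshold and presumed M-waves in triceps surae; electrode 4 (most
#' rostral) elicits nothing. Reflex suppression is 0.85 and M-wave
#' suppression 0.05, so recovered labels are unambiguous; noise SD is 4 uV
#' and the stimulation artifact 1500 uV (artifact-to-noise far above the
#' detection threshold).
#'
#' @param cfg A [tscs_protocol()] configuration (defines positions/muscles).
#' @param recruitment Optional tibble overriding the per-(muscle, electrode)
#'   truth; columns `muscle`, `electrode_position`, `type`
#'   (`reflex`/`m_wave`/`none`), `threshold_mA`, `suppression`,
#'   `latency_ms`, `max_amp_uV`.
#' @param noise_sd_uV Gaussian noise standard deviation, microvolts.
#' @param mains_uV Amplitude of an added 45 Hz interference component,
#'   microvolts (exercises the band-stop filter).
#' @param artifact_uV Stimulation-artifact spike amplitude, microvolts.
#' @param artifact_position_scale Optional named numeric vector scaling the
#'   artifact per electrode position (values near 0 yield baseline sweeps).
#' @param corrupt_rate Fraction of repetitions corrupted by a large
#'   low-frequency movement artifact (exercises the similarity gate).
#' @param corrupt_uV Amplitude of the movement artifact, microvolts.
#' @return A list of class `"tscs_sim_truth"`.
#' @export
tscs_sim_truth <- function(cfg = tscs_protocol(),
                           recruitment = NULL,
                           noise_sd_uV = 4,
                           mains_uV = 3,
                           artifact_uV = 1500,
                           artifact_position_scale = NULL,
                           corrupt_rate = 0,
                           corrupt_uV = 400) {
  if (is.null(recruitment)) recruitment <- default_sim_recruitment(cfg)
  need <- c("muscle", "electrode_position", "type", "threshold_mA",
            "suppression", "latency_ms", "max_amp_uV")
  miss <- setdiff(need, names(recruitment))
  if (length(miss))
    abort(paste0("recruitment truth lacks columns: ",
                 paste(miss, collapse = ", ")))
  bad <- recruitment$type == "reflex" & recruitment$suppression <= 0.60 |
    recruitment$type == "m_wave" & recruitment$suppression > 0.60
  if (any(bad))
    abort("truth inconsistency: reflex suppression must exceed 0.60 and m_wave suppression must not")
  if (is.null(artifact_position_scale))
    artifact_position_scale <- setNames(rep(1, length(cfg$electrode_positions)),
                                        cfg$electrode_positions)
  truth <- list(recruitment = as_tibble(recruitment),
                noise_sd_uV = noise_sd_uV, mains_uV = mains_uV,
                artifact_uV = artifact_uV,
                artifact_position_scale = artifact_position_scale,
                corrupt_rate = corrupt_rate, corrupt_uV = corrupt_uV)
  class(truth) <- "tscs_sim_truth"
  truth
}

default_sim_recruitment <- function(cfg) {
  pos <- cfg$electrode_positions
  base <- tidyr::expand_grid(muscle = cfg$muscles, electrode_position = pos)
  # caudal→rostral recruitment pattern; quadriceps latency ~12 ms, triceps
  # surae ~20 ms (longer conduction path)
  per_pos <- list(
    "1" = c(LQ = "none", RQ = "none", LTS = "reflex", RTS = "reflex"),
    "2" = c(LQ = "reflex", RQ = "reflex", LTS = "reflex", RTS = "reflex"),
    "3" = c(LQ = "reflex", RQ = "reflex", LTS = "m_wave", RTS = "m_wave"),
    "4" = c(LQ = "none", RQ = "none", LTS = "none", RTS = "none"))
  thr_pos <- c("1" = 50, "2" = NA, "3" = 55, "4" = Inf)
  base |>
    mutate(
      type = map2_chr_safe(.data$muscle, .data$electrode_position, per_pos),
      threshold_mA = dplyr::case_when(
        .data$electrode_position == 2 & .data$muscle %in% c("LTS", "RTS") ~ 40,
        .data$electrode_position == 2 ~ 45,
        .data$electrode_position == 3 & .data$muscle %in% c("LTS", "RTS") ~ 50,
        TRUE ~ unname(thr_pos[as.character(.data$electrode_position)])),
      threshold_mA = ifelse(.data$type == "none", Inf, .data$threshold_mA),
      suppression = dplyr::case_when(.data$type == "reflex" ~ 0.85,
                                     .data$type == "m_wave" ~ 0.05,
                                     TRUE ~ 0),
      latency_ms = ifelse(grepl("Q$", .data$muscle), 12, 20),
      max_amp_uV = ifelse(.data$type == "none", 0, 400))
}

map2_chr_safe <- function(muscle, pos, per_pos) {
  vapply(seq_along(muscle), function(i) {
    p <- as.character(pos[i])
    if (!p %in% names(per_pos)) return("none")
    unname(per_pos[[p]][muscle[i]])
  }, character(1))
}

#' Simulate a raw calibration session with known ground truth
#'
#' Generates one raw 600-sample sweep per (electrode position, amplitude,
#' repetition) and muscle channel: Gaussian noise plus optional 45 Hz
#' interference, two biphasic stimulation-artifact spikes (`+A` then `-A`)
#' at a jittered onset and one inter-pulse interval later, a first evoked
#' response scaled by the sigmoid recruitment curve, and a second response
#' scaled by `1 - suppression`. The onset is jittered uniformly over samples
#' 31-81 so the synchronizer is genuinely exercised while a full crop window
#' always exists. Optionally, repetitions are corrupted at rate
#' `corrupt_rate` by a large stimulus-locked low-frequency movement burst
#' (confined to the first 90 ms after the stimulus) to exercise the
#' similarity gate. Fully reproducible for a given seed.
#'
#' @param truth A [tscs_sim_truth()] object.
#' @param cfg A [tscs_protocol()] configuration.
#' @param seed Integer seed.
#' @param sweep_samples Raw sweep length in samples.
#' @return A session tibble (see [read_tscs_session()]) with attribute
#'   `"truth"` carrying the ground-truth ledger, including the expected
#'   rating label per cell (`expected_rating`), per-electrode expected
#'   thresholds (`expected_thresholds`), and the expected best electrode.
#' @examples
#' cfg <- tscs_protocol(electrode_positions = 1:2, amplitudes_mA = c(5, 10))
#' sess <- tscs_simulate_session(tscs_sim_truth(cfg), cfg, seed = 42)
#' @export
tscs_simulate_session <- function(truth = tscs_sim_truth(cfg),
                                  cfg = tscs_protocol(),
                                  seed = 1L,
                                  sweep_samples = 600L) {
  stopifnot(inherits(truth, "tscs_sim_truth"))
  if (sweep_samples < 81L + ipi_samples(cfg) + 2L)
    abort("sweep_samples too short for the jittered double stimulus")
  set.seed(seed)
  fs <- cfg$fs_hz
  off <- ipi_samples(cfg)
  t_ms <- (seq_len(sweep_samples) - 1L) * 1000 / fs
  rec_key <- paste(truth$recruitment$muscle,
                   truth$recruitment$electrode_position)
  rec_rows <- setNames(seq_len(nrow(truth$recruitment)), rec_key)

  grid <- tidyr::expand_grid(
    electrode_position = cfg$electrode_positions,
    amplitude_mA = cfg$amplitudes_mA,
    repetition = seq_len(cfg$repetitions))

  rows <- vector("list", nrow(grid) * length(cfg$muscles))
  corrupted_flags <- logical(nrow(grid))
  k <- 0L
  for (s in seq_len(nrow(grid))) {
    n <- grid$electrode_position[s]
    I <- grid$amplitude_mA[s]
    j <- grid$repetition[s]
    onset <- sample(31:81, 1L)
    corrupted <- runif(1) < truth$corrupt_rate
    corrupted_flags[s] <- corrupted
    a_scale <- truth$artifact_position_scale[as.character(n)]
    if (is.na(a_scale)) a_scale <- 1
    A <- truth$artifact_uV * a_scale
    for (m in cfg$muscles) {
      tr <- truth$recruitment[rec_rows[[paste(m, n)]], ]
      x <- rnorm(sweep_samples, 0, truth$noise_sd_uV)
      if (truth$mains_uV > 0)
        x <- x + truth$mains_uV * sin(2 * pi * 45 * t_ms / 1000 +
                                        runif(1, 0, 2 * pi))
      # two biphasic artifact spikes, one inter-pulse interval apart
      x[onset] <- x[onset] + A
      x[onset + 1L] <- x[onset + 1L] - A
      x[onset + off] <- x[onset + off] + A
      x[onset + off + 1L] <- x[onset + off + 1L] - A
      amp1 <- if (is.finite(tr$threshold_mA))
        tscs_recruitment(I, tr$threshold_mA, tr$max_amp_uV) else 0
      if (amp1 > 0) {
        rel <- t_ms - (onset - 1L) * 1000 / fs
        w1 <- tscs_response_waveform(rel, tr$latency_ms, amp1)
        w2 <- tscs_response_waveform(rel - cfg$ipi_ms, tr$latency_ms,
                                     amp1 * (1 - tr$suppression))
        x <- x + w1 + w2
      }
      if (corrupted) {
        # stimulus-locked movement burst confined to the first 90 ms after
        # the stimulus: it floods the similarity windows (5-95 ms) while
        # leaving the 100-300 ms noise-profiling window untouched
        tau <- 0:90
        burst <- truth$corrupt_uV * runif(1, 0.6, 1.4) *
          sin(pi * tau / 90) * sin(2 * pi * runif(1, 8, 15) * tau / 1000 +
                                     runif(1, 0, 2 * pi))
        x[onset + tau] <- x[onset + tau] + burst
      }
      k <- k + 1L
      rows[[k]] <- tibble(electrode_position = n, amplitude_mA = I,
                          repetition = j, muscle = m, samples = list(x))
    }
  }
  session <- bind_rows(rows)
  ledger <- sim_truth_ledger(truth, cfg, seed)
  ledger$corrupted_sweeps <- mutate(grid, corrupted = corrupted_flags)
  attr(session, "truth") <- ledger
  session
}

# Expected pipeline outcome implied by the ground truth: per-cell rating
# labels, per-electrode thresholds, and the best electrode under both
# recommendation methods.
sim_truth_ledger <- function(truth, cfg, seed) {
  cells <- tidyr::expand_grid(
    muscle = cfg$muscles,
    electrode_position = cfg$electrode_positions,
    amplitude_mA = cfg$amplitudes_mA) |>
    left_join(truth$recruitment, by = c("muscle", "electrode_position")) |>
    mutate(
      amp1_uV = ifelse(is.finite(.data$threshold_mA),
                       tscs_recruitment(.data$amplitude_mA,
                                        pmin(.data$threshold_mA, 1e6),
                                        .data$max_amp_uV), 0),
      responded = .data$amp1_uV > cfg$min_amp_uV &
        .data$amp1_uV > cfg$noise_sd_factor * truth$noise_sd_uV,
      expected_label = dplyr::case_when(
        !.data$responded ~ "no_response",
        .data$suppression > cfg$suppression_threshold ~ "reflex",
        TRUE ~ "m_wave"))
  thresholds <- cells |>
    group_by(.data$electrode_position) |>
    summarise(threshold_mA = {
      g <- .data$amplitude_mA[.data$expected_label == "reflex"]
      if (length(g)) min(g) else NA_real_
    }, .groups = "drop")
  greens <- cells |>
    group_by(.data$electrode_position, .data$amplitude_mA) |>
    summarise(green_count = sum(.data$expected_label == "reflex"),
              .groups = "drop") |>
    filter(.data$green_count >= cfg$min_green_muscles) |>
    left_join(thresholds, by = "electrode_position") |>
    arrange(desc(.data$green_count),
            .data$amplitude_mA - .data$threshold_mA,
            .data$amplitude_mA, .data$electrode_position)
  best <- if (nrow(greens)) greens$electrode_position[1] else NA_integer_
  list(truth = truth, seed = seed,
       expected_rating = select(cells, "muscle", "electrode_position",
                                "amplitude_mA", "expected_label"),
       expected_thresholds = thresholds,
       expected_best_electrode = best)
}
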