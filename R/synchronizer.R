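#' Non-causal double differentiation of an EMG signal
#'
#' Applies a discrete approximation of the Laplace operator, scaled by four:
#' `4 * (x[k-1] - 2*x[k] + x[k+1])`. Stimulation artifacts — near-discontinuous
#' jumps riding on comparatively smooth EMG — stand out sharply in this
#' signal. The first and last sample, where the stencil is incomplete, are set
#' to zero; artifact candidates are restricted to the interior of the sweep,
#' so the edges never participate.
#'
#' @param x Numeric vector (microvolts), length at least 3.
#' @return Numeric vector of the same length.
#' @examples
#' tscs_double_difference(c(0, 0, 1, 0, 0))
#' @export
tscs_double_difference <- function(x) {
  n <- length(x)
  if (n < 3L) abort("double differentiation needs at least 3 samples")
  d <- numeric(n)
  d[2:(n - 1L)] <- 4 * (x[1:(n - 2L)] - 2 * x[2:(n - 1L)] + x[3:n])
  d
}

# Per-channel artifact candidate scan. Returns list(candidates, any_c1).
# A sample t (1-based) is a candidate iff
#   C1: |d[t]|       > k * SD(d[tail_window])
#   C2: |d[t + ipi]| > k * SD(d[tail_window])    (second pulse's artifact)
#   C3: |d[t + 2*ipi]| <= threshold              (no third artifact)
#   C4: the median-free raw signal changes sign at t vs t-1 or t vs t+1
# with ipi the inter-pulse interval in samples and the scan limited to the
# configured search window.
artifact_candidates <- function(x, cfg) {
  n <- length(x)
  d <- tscs_double_difference(x)
  tail_idx <- intersect(seq.int(cfg$tail_window[1], cfg$tail_window[2]),
                        seq_len(n))
  if (length(tail_idx) < 2L)
    abort("sweep too short: dispersion tail window is empty")
  thr <- cfg$detection_sd_factor * sd(d[tail_idx])
  c1 <- abs(d) > thr
  off <- ipi_samples(cfg)

  mf <- x - median(x)
  sgn <- sign(mf)
  scan <- intersect(seq.int(cfg$search_window[1], cfg$search_window[2]),
                    seq_len(n))
  cand <- scan[vapply(scan, function(t) {
    if (!c1[t]) return(FALSE)
    if (t + off > n || !c1[t + off]) return(FALSE)
    if (t + 2L * off <= n && c1[t + 2L * off]) return(FALSE)
    chg_prev <- t > 1L && sgn[t] != sgn[t - 1L]
    chg_next <- t < n && sgn[t] != sgn[t + 1L]
    chg_prev || chg_next
  }, logical(1))]
  list(candidates = cand, any_c1 = any(c1))
}

#' Detect the first stimulation artifact in a raw paired-pulse sweep
#'
#' Scans the double-differentiated quadriceps channels for samples at which a
#' super-threshold deflection recurs exactly one inter-pulse interval later
#' but not two intervals later, and at which the median-free raw signal
#' changes sign — the signature of the first of the two biphasic stimulation
#' artifacts. The threshold is a multiple (default 3) of the standard
#' deviation of the double-differentiated signal over a late, stimulus-free
#' tail of the sweep, so detection is invariant to overall signal scale. The
#' earliest candidate within the search window (default samples 10-200) wins;
#' when both detection channels yield candidates the earlier onset is taken,
#' with ties resolved in favor of the first-listed channel.
#'
#' @param channels Named list of numeric vectors, one per muscle; must contain
#'   the configured detection channels (default LQ and RQ).
#' @param cfg A [tscs_protocol()] configuration.
#' @return A list with `status` (`"aligned"`, `"baseline"`, or
#'   `"discarded"`) and `onset` (1-based sample index of the first stimulus,
#'   `NA` unless aligned). A sweep is `baseline` when the threshold condition
#'   holds for no sample on any detection channel, and `discarded` when
#'   super-threshold samples exist but no full candidate does.
#' @export
tscs_detect_artifact <- function(channels, cfg = tscs_protocol()) {
  det <- cfg$detection_channels
  miss <- setdiff(det, names(channels))
  if (length(miss))
    abort(paste0("detection channel(s) missing from sweep: ",
                 paste(miss, collapse = ", ")))
  res <- lapply(channels[det], artifact_candidates, cfg = cfg)
  onsets <- map_dbl(res, ~ if (length(.x$candidates)) min(.x$candidates) else Inf)
  if (any(is.finite(onsets))) {
    # earliest onset across channels; which.min keeps the first-listed
    # channel on ties
    return(list(status = "aligned", onset = as.integer(onsets[which.min(onsets)])))
  }
  if (!any(map_lgl(res, "any_c1")))
    return(list(status = "baseline", onset = NA_integer_))
  list(status = "discarded", onset = NA_integer_)
}

#' Re-time a sweep so that the first stimulus sits at t = 0
#'
#' Crops every channel of a sweep to the configured window around the
#' detected first stimulus (default -30 to 300 ms, i.e. 331 samples at
#' 1 kHz). Both sensor groups are re-timed to the common onset. Sweeps whose
#' onset lies too close to either end of the recording for the full window to
#' exist are discarded — downstream measurement windows extend to 300 ms and
#' must be present. For baseline sweeps the first `aligned_length` samples
#' are extracted unchanged (they carry noise information only).
#'
#' @param channels Named list of numeric channel vectors.
#' @param onset 1-based sample index of the first stimulus (from
#'   [tscs_detect_artifact()]), or `NA` for baseline sweeps.
#' @param cfg A [tscs_protocol()] configuration.
#' @param status `"aligned"` or `"baseline"`.
#' @return A list with `status`, `onset`, and `channels` (each cropped to the
#'   aligned window; `NULL` channels if the sweep had to be discarded). The
#'   time axis of aligned channels runs from `crop_window_ms[1]` to
#'   `crop_window_ms[2]`, onset at t = 0.
#' @export
tscs_align_sweep <- function(channels, onset, cfg = tscs_protocol(),
                             status = "aligned") {
  len <- aligned_length(cfg)
  if (identical(status, "baseline")) {
    n <- min(lengths(channels))
    if (n < len) return(list(status = "discarded", onset = NA_integer_,
                             channels = NULL))
    return(list(status = "baseline", onset = NA_integer_,
                channels = lapply(channels, function(x) x[seq_len(len)])))
  }
  pre <- as.integer(round(-cfg$crop_window_ms[1] * cfg$fs_hz / 1000))
  post <- as.integer(round(cfg$crop_window_ms[2] * cfg$fs_hz / 1000))
  first <- onset - pre
  last <- onset + post
  n <- min(lengths(channels))
  if (is.na(onset) || first < 1L || last > n)
    return(list(status = "discarded", onset = NA_integer_, channels = NULL))
  list(status = "aligned", onset = onset,
       channels = lapply(channels, function(x) x[first:last]))
}

#' Synchronize every sweep of a session to its first stimulus
#'
#' Runs artifact detection ([tscs_detect_artifact()]) and re-timing
#' ([tscs_align_sweep()]) over all (electrode, amplitude, repetition) sweeps
#' of a session. Each sweep is classified as `aligned` (first stimulus found
#' and full crop window available), `baseline` (no super-threshold
#' deflection anywhere — typical for low amplitudes and the most rostral
#' electrode, retained for noise profiling), or `discarded`.
#'
#' @param session A session tibble from [read_tscs_session()] or
#'   [tscs_simulate_session()].
#' @param cfg A [tscs_protocol()] configuration.
#' @return A tibble with one row per sweep channel: `electrode_position`,
#'   `amplitude_mA`, `repetition`, `muscle`, `status`, `onset` (1-based raw
#'   sample index of the first stimulus), and `samples` (cropped series;
#'   `NULL` for discarded sweeps).
#' @export
tscs_synchronize <- function(session, cfg = tscs_protocol()) {
  validate_tscs_session(session, cfg)
  sweeps <- session |>
    group_by(.data$electrode_position, .data$amplitude_mA, .data$repetition) |>
    tidyr::nest(channels = c("muscle", "samples")) |>
    ungroup()

  aligned <- pmap(
    list(sweeps$channels),
    function(ch) {
      chl <- setNames(ch$samples, ch$muscle)
      det <- tscs_detect_artifact(chl, cfg)
      al <- tscs_align_sweep(chl, det$onset, cfg, status = det$status)
      tibble(
        muscle = ch$muscle,
        status = al$status,
        onset = if (identical(al$status, "aligned")) al$onset else NA_integer_,
        samples = if (is.null(al$channels)) list(NULL)[rep(1, nrow(ch))]
                  else unname(al$channels[ch$muscle])
      )
    })

  sweeps |>
    mutate(aligned = aligned) |>
    select(-"channels") |>
    tidyr::unnest("aligned")
}
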