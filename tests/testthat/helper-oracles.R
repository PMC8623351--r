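# Independent oracles and fixture builders used across the suite.

# Literal per-sample evaluation of the four artifact-candidate conditions,
# written as a plain loop, independent of the vectorized implementation.
brute_force_candidates <- function(x, cfg = tscs_protocol()) {
  n <- length(x)
  d <- numeric(n)
  for (k in 2:(n - 1)) d[k] <- 4 * (x[k - 1] - 2 * x[k] + x[k + 1])
  tail_idx <- intersect(seq(cfg$tail_window[1], cfg$tail_window[2]), 1:n)
  thr <- cfg$detection_sd_factor * stats::sd(d[tail_idx])
  off <- as.integer(round(cfg$ipi_ms * cfg$fs_hz / 1000))
  mf <- x - stats::median(x)
  out <- integer(0)
  for (t in seq(cfg$search_window[1], min(cfg$search_window[2], n))) {
    c1 <- abs(d[t]) > thr
    c2 <- (t + off <= n) && abs(d[t + off]) > thr
    c3 <- (t + 2 * off > n) || abs(d[t + 2 * off]) <= thr
    c4 <- (t > 1 && sign(mf[t]) != sign(mf[t - 1])) ||
      (t < n && sign(mf[t]) != sign(mf[t + 1]))
    if (c1 && c2 && c3 && c4) out <- c(out, t)
  }
  out
}

# Raw sweep: smooth deterministic background plus optional biphasic artifact
# spikes one inter-pulse interval apart. The 3 Hz background guarantees a
# nonzero dispersion estimate while never triggering the detector by itself.
make_artifact_sweep <- function(onset = NULL, n = 600, artifact_uV = 500,
                                background_uV = 10, noise_uV = 0,
                                second = TRUE, ipi = 50) {
  t <- seq_len(n)
  x <- background_uV * sin(2 * pi * 3 * (t - 1) / 1000)
  if (noise_uV > 0) x <- x + stats::rnorm(n, 0, noise_uV)
  if (!is.null(onset)) {
    x[onset] <- x[onset] + artifact_uV
    x[onset + 1] <- x[onset + 1] - artifact_uV
    if (second) {
      x[onset + ipi] <- x[onset + ipi] + artifact_uV
      x[onset + ipi + 1] <- x[onset + ipi + 1] - artifact_uV
    }
  }
  x
}

# Brute-force lexicographic ordering of candidate (electrode, amplitude)
# pairs via base::order on the four nested keys.
rank_oracle <- function(cells, thresholds, min_green = 2L) {
  agg <- aggregate(green ~ n + I, data = cells, FUN = sum)
  agg <- agg[agg$green >= min_green, , drop = FALSE]
  if (nrow(agg) == 0) return(agg)
  agg$thr <- thresholds$threshold_mA[match(agg$n, thresholds$electrode_position)]
  agg$delta <- agg$I - agg$thr
  agg <- agg[order(-agg$green, agg$delta, agg$I, agg$n), , drop = FALSE]
  agg$rank <- seq_len(nrow(agg))
  agg
}

# Random rating tibble over a small grid: every cell labeled, greens placed
# at random, invalid cells possible.
random_rating <- function(n_pos = 3, n_amp = 5, p_green = 0.25,
                          p_invalid = 0.05) {
  grid <- expand.grid(muscle = c("LQ", "LTS", "RQ", "RTS"),
                      electrode_position = seq_len(n_pos),
                      amplitude_mA = seq(5, by = 5, length.out = n_amp),
                      stringsAsFactors = FALSE)
  u <- stats::runif(nrow(grid))
  grid$label <- ifelse(u < p_invalid, "invalid",
                       ifelse(u < p_invalid + p_green, "reflex",
                              ifelse(u < p_invalid + p_green + 0.1,
                                     "m_wave", "no_response")))
  grid$amp1_uV <- ifelse(grid$label == "invalid", NA_real_,
                         ifelse(grid$label == "no_response",
                                stats::runif(nrow(grid), 0, 40),
                                stats::runif(nrow(grid), 60, 500)))
  grid$amp2_uV <- ifelse(is.na(grid$amp1_uV), NA_real_,
                         grid$amp1_uV * stats::runif(nrow(grid)))
  grid$suppression <- ifelse(is.na(grid$amp1_uV), NA_real_,
                             tscs_suppression(grid$amp1_uV, grid$amp2_uV))
  grid$color <- c(no_response = "gray", reflex = "green", m_wave = "yellow",
                  invalid = "red")[grid$label]
  grid$n_averaged <- ifelse(grid$label == "invalid", 0L, 3L)
  out <- tibble::as_tibble(grid)
  class(out) <- c("tscs_rating", class(out))
  out
}

# Hand-constructed rating tibble from a compact spec: data frame with
# muscle, n, I, label, and optional amp1/sup.
rating_from_spec <- function(df) {
  df$amp1_uV <- if ("amp1_uV" %in% names(df)) df$amp1_uV else
    ifelse(df$label == "invalid", NA_real_,
           ifelse(df$label == "no_response", 10, 200))
  df$amp2_uV <- ifelse(is.na(df$amp1_uV), NA_real_, 0)
  df$suppression <- if ("suppression" %in% names(df)) df$suppression else
    ifelse(df$label == "invalid", NA_real_,
           ifelse(df$label == "reflex", 0.9,
                  ifelse(df$label == "m_wave", 0.2, 0)))
  df$color <- c(no_response = "gray", reflex = "green", m_wave = "yellow",
                invalid = "red")[df$label]
  df$n_averaged <- ifelse(df$label == "invalid", 0L, 3L)
  out <- tibble::as_tibble(df)
  class(out) <- c("tscs_rating", class(out))
  out
}

# Small protocol for fast tests.
small_cfg <- function(positions = 1:2, amps = seq(5, 30, by = 5)) {
  tscs_protocol(electrode_positions = positions, amplitudes_mA = amps)
}
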