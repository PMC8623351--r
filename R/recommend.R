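#' Per-electrode reflex amplitude thresholds
#'
#' The amplitude threshold I' of an electrode position is the lowest
#' stimulation amplitude on the grid at which any muscle is rated as a reflex
#' response (green). Electrodes that never elicit a reflex have `NA`.
#'
#' @param rating A rating tibble from [tscs_rate()].
#' @return A tibble with columns `electrode_position` and `threshold_mA`.
#' @export
tscs_amplitude_thresholds <- function(rating) {
  rating |>
    group_by(.data$electrode_position) |>
    summarise(threshold_mA = {
      g <- .data$amplitude_mA[.data$label == "reflex"]
      if (length(g)) min(g) else NA_real_
    }, .groups = "drop")
}

#' Lexicographic ranking of (electrode, amplitude) pairs
#'
#' Ranks every (electrode position, stimulation amplitude) pair that elicits
#' reflex responses in at least `min_green_muscles` muscles (the minimal
#' requirement, default two of four) by a nested search: (1) the largest
#' number of reflex-positive muscles; (2) the smallest difference between the
#' stimulation amplitude and the electrode's amplitude threshold I'; (3) the
#' lowest stimulation amplitude. Residual ties are broken toward the lower
#' (more caudal) electrode position. Rank 1 is best.
#'
#' @param rating A rating tibble from [tscs_rate()].
#' @param thresholds Threshold tibble from [tscs_amplitude_thresholds()];
#'   recomputed when `NULL`.
#' @param cfg A [tscs_protocol()] configuration.
#' @return A tibble of `RankEntry` rows: `rank`, `electrode_position`,
#'   `amplitude_mA`, `green_count`, `delta_threshold_mA`. Empty when no pair
#'   meets the minimal requirement.
#' @export
tscs_rank_pairs <- function(rating, thresholds = NULL, cfg = tscs_protocol()) {
  if (is.null(thresholds)) thresholds <- tscs_amplitude_thresholds(rating)
  rating |>
    group_by(.data$electrode_position, .data$amplitude_mA) |>
    summarise(green_count = sum(.data$label == "reflex"), .groups = "drop") |>
    filter(.data$green_count >= cfg$min_green_muscles) |>
    left_join(thresholds, by = "electrode_position") |>
    mutate(delta_threshold_mA = .data$amplitude_mA - .data$threshold_mA) |>
    arrange(desc(.data$green_count), .data$delta_threshold_mA,
            .data$amplitude_mA, .data$electrode_position) |>
    mutate(rank = row_number()) |>
    select("rank", "electrode_position", "amplitude_mA", "green_count",
           "delta_threshold_mA")
}

#' Normalized cost function over (electrode, amplitude) pairs
#'
#' For each pair, `J(n, I)` is the mean over muscles of the first-response
#' amplitude normalized by that muscle's maximal first-response amplitude
#' anywhere in the session, scaled by the observed suppression ratio:
#' `J = mean_i( amp1_i(n,I) / max_amp1_i * sup_i(n,I) )`. Large values favor
#' electrode positions yielding strongly suppressed (reflex) responses of
#' large amplitude in many muscles. Invalid cells and muscles without any
#' response contribute zero; `J` lies in `[0, 1]`.
#'
#' @param rating A rating tibble from [tscs_rate()].
#' @param cfg A [tscs_protocol()] configuration.
#' @return A tibble with `electrode_position`, `amplitude_mA`, `J`, plus the
#'   per-muscle normalizers as attribute `"normalizers"` (tibble `muscle`,
#'   `max_amp1_uV`).
#' @export
tscs_cost_scores <- function(rating, cfg = tscs_protocol()) {
  normalizers <- rating |>
    group_by(.data$muscle) |>
    summarise(max_amp1_uV = {
      a <- .data$amp1_uV[!is.na(.data$amp1_uV)]
      if (length(a)) max(a) else 0
    }, .groups = "drop")
  norm_lookup <- setNames(normalizers$max_amp1_uV, normalizers$muscle)
  n_muscles <- length(unique(rating$muscle))
  scores <- rating |>
    mutate(contrib = ifelse(
      is.na(.data$amp1_uV) | norm_lookup[.data$muscle] <= 0, 0,
      .data$amp1_uV / norm_lookup[.data$muscle] * .data$suppression)) |>
    group_by(.data$electrode_position, .data$amplitude_mA) |>
    summarise(J = sum(.data$contrib) / n_muscles, .groups = "drop")
  attr(scores, "normalizers") <- normalizers
  scores
}

# Floor an amplitude to the grid; NA when below the lowest grid value.
floor_to_grid <- function(x, grid) {
  ok <- grid[grid <= x + 1e-9]
  if (length(ok)) max(ok) else NA_real_
}

therapy_amplitude <- function(threshold_mA, cfg) {
  raw <- cfg$therapy_fraction * threshold_mA
  if (identical(cfg$rounding, "grid")) floor_to_grid(raw, cfg$amplitudes_mA)
  else raw
}

#' Recommend an electrode position and therapy amplitude
#'
#' Combines the lexicographic ranking and the cost-function scoring into the
#' final therapy recommendation. The ranking method selects the electrode of
#' the rank-1 pair; the cost method selects the electrode holding the
#' globally maximal `J`. Both methods set the therapy amplitude to
#' `therapy_fraction` (default 90%) of the selected electrode's amplitude
#' threshold I', floored to the amplitude grid by default — guaranteeing
#' sub-threshold stimulation as used for spasticity control. When no pair
#' meets the minimal requirement the recommendation is absent with an
#' explicit reason.
#'
#' @param rating A rating tibble from [tscs_rate()].
#' @param cfg A [tscs_protocol()] configuration.
#' @return An object of class `"tscs_recommendation"`: a list with `status`
#'   (`"ok"` or `"none"`), `reason`, per-method results `ranking` and `cost`
#'   (each with `electrode_position`, `threshold_mA`, `therapy_mA`),
#'   `agreement` (logical), `thresholds`, `rank_table`, `cost_table`.
#' @examples
#' cfg <- tscs_protocol(electrode_positions = 1:2, amplitudes_mA = c(5, 10))
#' sess <- tscs_simulate_session(tscs_sim_truth(cfg), cfg, seed = 1)
#' # (typically reached via tscs_calibrate(); see that help page)
#' @export
tscs_recommend <- function(rating, cfg = tscs_protocol()) {
  thresholds <- tscs_amplitude_thresholds(rating)
  ranks <- tscs_rank_pairs(rating, thresholds, cfg)
  costs <- tscs_cost_scores(rating, cfg)
  thr_lookup <- setNames(thresholds$threshold_mA,
                         thresholds$electrode_position)

  if (nrow(ranks) == 0) {
    rec <- list(
      status = "none",
      reason = paste0("no (electrode, amplitude) pair elicited reflex ",
                      "responses in at least ", cfg$min_green_muscles,
                      " muscles"),
      ranking = NULL, cost = NULL, agreement = NA,
      thresholds = thresholds, rank_table = ranks, cost_table = costs)
    class(rec) <- "tscs_recommendation"
    return(rec)
  }

  n_rank <- ranks$electrode_position[1]
  method_result <- function(n) {
    thr <- unname(thr_lookup[as.character(n)])
    list(electrode_position = n, threshold_mA = thr,
         therapy_mA = if (is.na(thr)) NA_real_ else therapy_amplitude(thr, cfg))
  }

  best_cost <- costs |> arrange(desc(.data$J), .data$electrode_position,
                                .data$amplitude_mA)
  n_cost <- best_cost$electrode_position[1]

  rec <- list(
    status = "ok", reason = NA_character_,
    ranking = method_result(n_rank),
    cost = c(method_result(n_cost), list(J = best_cost$J[1])),
    agreement = identical(as.integer(n_rank), as.integer(n_cost)),
    thresholds = thresholds,
    rank_table = ranks,
    cost_table = costs)
  class(rec) <- "tscs_recommendation"
  rec
}

#' @export
print.tscs_recommendation <- function(x, ...) {
  cat("<tscs_recommendation>\n")
  if (identical(x$status, "none")) {
    cat("  no recommendation:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("  ranking approach: electrode %d, threshold %g mA, therapy %g mA\n",
              x$ranking$electrode_position, x$ranking$threshold_mA,
              x$ranking$therapy_mA))
  cat(sprintf("  cost approach:    electrode %d, threshold %g mA, therapy %g mA (J = %.3f)\n",
              x$cost$electrode_position, x$cost$threshold_mA,
              x$cost$therapy_mA, x$cost$J))
  cat("  methods agree on electrode:", x$agreement, "\n")
  invisible(x)
}

#' Tidy a therapy recommendation
#'
#' `tidy()` returns one row per recommendation method with the selected
#' electrode, threshold, and therapy amplitude; `glance()` returns a one-row
#' session summary.
#'
#' @param x A `"tscs_recommendation"` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tscs_recommendation <- function(x, ...) {
  if (identical(x$status, "none")) {
    return(tibble(method = c("ranking", "cost"),
                  electrode_position = NA_integer_, threshold_mA = NA_real_,
                  therapy_mA = NA_real_, J = NA_real_))
  }
  tibble(
    method = c("ranking", "cost"),
    electrode_position = c(x$ranking$electrode_position,
                           x$cost$electrode_position),
    threshold_mA = c(x$ranking$threshold_mA, x$cost$threshold_mA),
    therapy_mA = c(x$ranking$therapy_mA, x$cost$therapy_mA),
    J = c(NA_real_, x$cost$J))
}

#' @rdname tidy.tscs_recommendation
#' @export
glance.tscs_recommendation <- function(x, ...) {
  tibble(
    status = x$status,
    n_candidates = nrow(x$rank_table),
    agreement = x$agreement,
    ranking_electrode = if (is.null(x$ranking)) NA_integer_
                        else x$ranking$electrode_position,
    cost_electrode = if (is.null(x$cost)) NA_integer_
                     else x$cost$electrode_position,
    therapy_mA = if (is.null(x$ranking)) NA_real_ else x$ranking$therapy_mA)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
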