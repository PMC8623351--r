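#' Read a calibration session from a long-format CSV file
#'
#' A session file holds one raw EMG sweep per (electrode position, stimulation
#' amplitude, repetition) and muscle channel, in long format with mandatory
#' header `electrode_position,amplitude_mA,repetition,muscle,sample_index,
#' value_uV` (UTF-8, `.` decimal separator, 1-based sample indices). The
#' reader nests each channel's samples into a list-column, checks sample
#' values for finiteness and duplicates, and warns about (electrode,
#' amplitude, repetition) combinations expected from `cfg` but absent from the
#' file (e.g. a protocol stopped early at the tolerance limit).
#'
#' @param path Path to the session CSV.
#' @param cfg A [tscs_protocol()] configuration.
#' @return A session tibble with columns `electrode_position`, `amplitude_mA`,
#'   `repetition`, `muscle`, and `samples` (list of numeric vectors in
#'   microvolts), one row per sweep channel.
#' @examples
#' cfg <- tscs_protocol(electrode_positions = 1:2, amplitudes_mA = c(5, 10))
#' sess <- tscs_simulate_session(tscs_sim_truth(cfg), cfg, seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_tscs_session(sess, f)
#' sess2 <- read_tscs_session(f, cfg)
#' @export
read_tscs_session <- function(path, cfg = tscs_protocol()) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      electrode_position = readr::col_integer(),
      amplitude_mA = readr::col_double(),
      repetition = readr::col_integer(),
      muscle = readr::col_character(),
      sample_index = readr::col_integer(),
      value_uV = readr::col_double()
    )
  )
  need <- c("electrode_position", "amplitude_mA", "repetition", "muscle",
            "sample_index", "value_uV")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    abort(paste0("session file lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0)
    abort(sprintf("malformed session file: %d parse problem(s), first at line %d (%s)",
                  nrow(probs), probs$row[1] + 1L, probs$expected[1]))
  if (anyNA(raw[need]) || any(!is.finite(raw$value_uV)))
    abort("session file contains missing or non-finite values")
  dup <- duplicated(raw[c("electrode_position", "amplitude_mA", "repetition",
                          "muscle", "sample_index")])
  if (any(dup)) {
    d <- raw[which(dup)[1], ]
    abort(sprintf(
      "integrity error: duplicate sample (n=%d, I=%g, j=%d, %s, t=%d)",
      d$electrode_position, d$amplitude_mA, d$repetition, d$muscle,
      d$sample_index))
  }

  session <- raw |>
    arrange(.data$electrode_position, .data$amplitude_mA, .data$repetition,
            .data$muscle, .data$sample_index) |>
    group_by(.data$electrode_position, .data$amplitude_mA, .data$repetition,
             .data$muscle) |>
    summarise(samples = list(.data$value_uV), .groups = "drop")

  validate_tscs_session(session, cfg)

  expected <- tidyr::expand_grid(
    electrode_position = cfg$electrode_positions,
    amplitude_mA = cfg$amplitudes_mA,
    repetition = seq_len(cfg$repetitions)
  )
  present <- distinct(session, .data$electrode_position, .data$amplitude_mA,
                      .data$repetition)
  gaps <- dplyr::anti_join(
    expected, present,
    by = c("electrode_position", "amplitude_mA", "repetition"))
  if (nrow(gaps) > 0) {
    warn(paste0(
      "session is missing ", nrow(gaps), " expected sweep(s): ",
      paste(sprintf("(n=%d, I=%g, j=%d)", gaps$electrode_position,
                    gaps$amplitude_mA, gaps$repetition), collapse = ", ")))
  }
  session
}

#' Write a calibration session to a long-format CSV file
#'
#' @param session A session tibble (see [read_tscs_session()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tscs_session <- function(session, path) {
  long <- session |>
    tidyr::unnest_longer("samples", values_to = "value_uV",
                         indices_to = "sample_index") |>
    select("electrode_position", "amplitude_mA", "repetition", "muscle",
           "sample_index", "value_uV")
  readr::write_csv(long, path)
  invisible(path)
}

validate_tscs_session <- function(session, cfg) {
  bad <- setdiff(unique(session$muscle), cfg$muscles)
  if (length(bad))
    abort(paste0("unknown muscle label(s): ", paste(bad, collapse = ", ")))
  ok <- map_lgl(session$samples, ~ is.numeric(.x) && all(is.finite(.x)))
  if (!all(ok)) abort("sweep samples must be finite numeric vectors")
  # channels within one sensor group of a sweep must share a length
  lens <- session |>
    mutate(group = unname(cfg$limb_grouping[.data$muscle]),
           len = lengths(.data$samples)) |>
    group_by(.data$electrode_position, .data$amplitude_mA, .data$repetition,
             .data$group) |>
    summarise(n_len = dplyr::n_distinct(.data$len), .groups = "drop")
  if (any(lens$n_len > 1))
    abort("channels within one sensor group must have equal length")
  invisible(session)
}
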