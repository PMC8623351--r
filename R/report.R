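#' Write a calibration report to disk
#'
#' Serializes the rating matrix and the recommendation as a machine-readable
#' JSON report (`report.json`, schema shipped under
#' `system.file("schema", "report.schema.json", package = "tscscalib")`) plus
#' a flat CSV rating table (`rating.csv`). The JSON report round-trips
#' losslessly through [read_tscs_report()]. An absent recommendation is
#' written as an explicit `null` result with the reason.
#'
#' @param rating A rating tibble from [tscs_rate()].
#' @param recommendation A `"tscs_recommendation"` from [tscs_recommend()].
#' @param dir Output directory (created if needed).
#' @param noise Optional noise profile tibble to embed.
#' @param dispositions Optional per-sweep disposition counts to embed.
#' @return Invisibly, the paths of the files written.
#' @export
write_tscs_report <- function(rating, recommendation, dir, noise = NULL,
                              dispositions = NULL) {
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(paste0("cannot create output directory: ", dir))
  json_path <- file.path(dir, "report.json")
  csv_path <- file.path(dir, "rating.csv")

  rec <- recommendation
  top5 <- utils::head(rec$rank_table, 5L)
  report <- list(
    rating = lapply(seq_len(nrow(rating)), function(i) {
      r <- rating[i, ]
      list(muscle = r$muscle, electrode_position = r$electrode_position,
           amplitude_mA = r$amplitude_mA, label = r$label, color = r$color,
           amp1_uV = r$amp1_uV, amp2_uV = r$amp2_uV,
           suppression = r$suppression, n_averaged = r$n_averaged)
    }),
    thresholds = df_to_records(rec$thresholds),
    rank_table = df_to_records(top5),
    cost_table = df_to_records(rec$cost_table),
    cost_normalizers = df_to_records(attr(rec$cost_table, "normalizers")),
    recommendation = if (identical(rec$status, "none")) {
      list(status = "none", reason = rec$reason, result = NULL)
    } else {
      list(status = "ok", reason = NULL,
           result = list(ranking = rec$ranking,
                         cost = rec$cost,
                         agreement = rec$agreement))
    },
    invalid_cell_ratio = mean(rating$label == "invalid"),
    noise_profile = if (is.null(noise)) NULL else df_to_records(noise),
    dispositions = dispositions
  )
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  readr::write_csv(rating, csv_path)
  invisible(c(json = json_path, csv = csv_path))
}

df_to_records <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(list())
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
}

#' Read a calibration report back from disk
#'
#' @param path Path to a `report.json` written by [write_tscs_report()].
#' @return A list with `rating` (tibble, same columns as [tscs_rate()]
#'   output), `thresholds`, `rank_table`, `cost_table`, `recommendation`,
#'   `invalid_cell_ratio`, and optional `noise_profile`.
#' @export
read_tscs_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  validate_tscs_report(raw)
  rating <- bind_rows(lapply(raw$rating, function(r) {
    tibble(muscle = r$muscle,
           electrode_position = as.integer(r$electrode_position),
           amplitude_mA = as.numeric(r$amplitude_mA),
           label = r$label, color = r$color,
           amp1_uV = null_na(r$amp1_uV), amp2_uV = null_na(r$amp2_uV),
           suppression = null_na(r$suppression),
           n_averaged = as.integer(r$n_averaged))
  }))
  class(rating) <- c("tscs_rating", class(rating))
  list(
    rating = rating,
    thresholds = records_to_df(raw$thresholds),
    rank_table = records_to_df(raw$rank_table),
    cost_table = records_to_df(raw$cost_table),
    cost_normalizers = records_to_df(raw$cost_normalizers),
    recommendation = raw$recommendation,
    invalid_cell_ratio = raw$invalid_cell_ratio,
    noise_profile = records_to_df(raw$noise_profile),
    dispositions = raw$dispositions
  )
}

null_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)

records_to_df <- function(recs) {
  if (is.null(recs) || length(recs) == 0) return(NULL)
  bind_rows(lapply(recs, function(r) as_tibble(lapply(r, \(v) v %||% NA))))
}

#' Validate a report against the shipped JSON schema
#'
#' Structural validation of a parsed report (or a report file) against the
#' JSON schema shipped with the package: checks required properties, value
#' types, and enumerations recursively. Errors name the offending field.
#'
#' @param report A parsed report list, or a path to a `report.json`.
#' @param schema_path Path to the schema; defaults to the shipped schema.
#' @return `TRUE`, invisibly, or an error naming the offending field.
#' @export
validate_tscs_report <- function(report,
                                 schema_path = system.file(
                                   "schema", "report.schema.json",
                                   package = "tscscalib")) {
  if (is.character(report) && length(report) == 1L)
    report <- jsonlite::read_json(report, simplifyVector = FALSE)
  schema <- jsonlite::read_json(schema_path, simplifyVector = FALSE)
  check_schema(report, schema, "report")
  invisible(TRUE)
}

# Minimal recursive checker for the schema subset used by the report:
# type (object/array/string/number/integer/boolean/null), properties,
# required, items, enum. Union types like ["number", "null"] are supported.
check_schema <- function(x, schema, where) {
  types <- schema$type
  if (!is.null(types)) {
    types <- unlist(types)
    ok <- any(vapply(types, function(ty) switch(
      ty,
      "object" = is.list(x) && (is.null(names(x)) == (length(x) == 0L) ||
                                  !is.null(names(x))),
      "array" = is.list(x) && is.null(names(x)),
      "string" = is.character(x) && length(x) == 1L,
      "number" = is.numeric(x) && length(x) == 1L,
      "integer" = is.numeric(x) && length(x) == 1L &&
        abs(x - round(x)) < 1e-9,
      "boolean" = is.logical(x) && length(x) == 1L,
      "null" = is.null(x),
      FALSE), logical(1)))
    if (!ok)
      abort(sprintf("report schema mismatch at %s: expected %s", where,
                    paste(types, collapse = "|")))
    if (is.null(x)) return(invisible(TRUE))
  }
  if (!is.null(schema$enum)) {
    if (!x %in% unlist(schema$enum))
      abort(sprintf("report schema mismatch at %s: value %s not in enum",
                    where, format(x)))
  }
  if (!is.null(schema$required)) {
    miss <- setdiff(unlist(schema$required), names(x))
    if (length(miss))
      abort(sprintf("report schema mismatch at %s: missing field(s) %s",
                    where, paste(miss, collapse = ", ")))
  }
  if (!is.null(schema$properties)) {
    for (nm in names(schema$properties)) {
      if (nm %in% names(x))
        check_schema(x[[nm]], schema$properties[[nm]],
                     paste0(where, ".", nm))
    }
  }
  if (!is.null(schema$items) && is.list(x) && is.null(names(x))) {
    for (i in seq_along(x))
      check_schema(x[[i]], schema$items, sprintf("%s[%d]", where, i))
  }
  invisible(TRUE)
}

#' Render a report as human-readable text tables
#'
#' Prints the rating-light matrix (one row per electrode position and
#' amplitude with the four muscle labels), the per-muscle first-response
#' amplitudes, the top-5 ranks, and the cost-function values — the textual
#' counterpart of the graphical rating-light and rating-details matrices.
#'
#' @param report A report list from [read_tscs_report()], or a path to a
#'   `report.json`.
#' @return The rendered lines, invisibly; called for its printed output.
#' @export
tscs_report_text <- function(report) {
  if (is.character(report)) report <- read_tscs_report(report)
  rating <- report$rating
  muscles <- unique(rating$muscle)
  rank_lookup <- list()
  if (!is.null(report$rank_table)) {
    rt <- report$rank_table
    rank_lookup <- setNames(as.list(rt$rank),
                            paste(rt$electrode_position, rt$amplitude_mA))
  }
  cost_lookup <- list()
  if (!is.null(report$cost_table)) {
    ct <- report$cost_table
    cost_lookup <- setNames(as.list(ct$J),
                            paste(ct$electrode_position, ct$amplitude_mA))
  }
  wide <- rating |>
    tidyr::pivot_wider(id_cols = c("electrode_position", "amplitude_mA"),
                       names_from = "muscle",
                       values_from = c("color", "amp1_uV")) |>
    arrange(.data$electrode_position, .data$amplitude_mA)

  lines <- c(sprintf("%3s %6s  %-38s %-34s %6s %8s", "n", "I[mA]",
                     paste(sprintf("%-9s", muscles), collapse = ""),
                     "amp1 [uV]", "rank", "J"))
  for (i in seq_len(nrow(wide))) {
    key <- paste(wide$electrode_position[i], wide$amplitude_mA[i])
    cols <- vapply(muscles, function(m) {
      sprintf("%-9s", wide[[paste0("color_", m)]][i])
    }, character(1))
    amps <- vapply(muscles, function(m) {
      a <- wide[[paste0("amp1_uV_", m)]][i]
      if (is.na(a)) " invalid" else sprintf("%8.1f", a)
    }, character(1))
    rk <- rank_lookup[[key]]
    jj <- cost_lookup[[key]]
    lines <- c(lines, sprintf(
      "%3d %6g  %-38s %-34s %6s %8s",
      wide$electrode_position[i], wide$amplitude_mA[i],
      paste(cols, collapse = ""), paste(amps, collapse = " "),
      if (is.null(rk)) "" else paste0("rank ", rk),
      if (is.null(jj)) "" else sprintf("%.3f", jj)))
  }
  rec <- report$recommendation
  if (identical(rec$status, "none")) {
    lines <- c(lines, "", paste0("NO CANDIDATE: ", rec$reason))
  } else {
    lines <- c(lines, "", sprintf(
      "ranking approach: electrode %d, threshold %g mA, therapy %g mA",
      rec$result$ranking$electrode_position, rec$result$ranking$threshold_mA,
      rec$result$ranking$therapy_mA), sprintf(
      "cost approach:    electrode %d, threshold %g mA, therapy %g mA",
      rec$result$cost$electrode_position, rec$result$cost$threshold_mA,
      rec$result$cost$therapy_mA))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
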