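#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join row_number desc across bind_rows distinct n pull rename
#' @importFrom purrr map map_dbl map_int map_lgl map2 pmap imap keep
#' @importFrom stats median sd rnorm runif setNames
NULL

# Convert a time in ms (relative to the first stimulus) to a 1-based sample
# index of a series whose first sample sits at `t_start_ms`.
ms_to_index <- function(t_ms, fs_hz, t_start_ms) {
  as.integer(round((t_ms - t_start_ms) * fs_hz / 1000)) + 1L
}

# Index range (1-based, clamped to [1, len]) for a closed ms window.
window_indices <- function(window_ms, fs_hz, t_start_ms, len) {
  i0 <- ms_to_index(window_ms[1], fs_hz, t_start_ms)
  i1 <- ms_to_index(window_ms[2], fs_hz, t_start_ms)
  if (i1 < 1L || i0 > len) return(integer(0))
  seq.int(max(1L, i0), min(len, i1))
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
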