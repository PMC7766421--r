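#' Sliding-window counts over a genomic or protein axis
#'
#' Windows are left-aligned at `span_start`, advance by `step_size`, and
#' count items by half-open membership `[start, start + window_size)`. Only
#' windows fully contained in `[span_start, span_end)` are emitted, so the
#' number of windows is `floor((span_length - window_size) / step_size) + 1`
#' (a trailing region shorter than one window is dropped unless
#' `include_partial = TRUE`). When the span is shorter than one window a
#' single truncated window is returned with a warning.
#'
#' @param positions numeric vector of item positions (genomic bp or protein
#'   aa), all within `[span_start, span_end)`.
#' @param span_start,span_end half-open span covered by the track.
#' @param window_size,step_size window and step, in axis units (> 0).
#' @param categories optional character vector parallel to `positions`; one
#'   additional count column is emitted per category level, sharing the same
#'   window grid.
#' @param include_partial also emit a final truncated window covering the
#'   trailing remainder.
#' @return `data.frame` with `window_start`, `window_end`, `count`, and one
#'   `count_<category>` column per category level.
#' @examples
#' window_counts(c(5, 15), 0, 20, window_size = 10, step_size = 10)
#' @export
window_counts <- function(positions, span_start, span_end, window_size,
                          step_size, categories = NULL,
                          include_partial = FALSE) {
  if (window_size <= 0 || step_size <= 0)
    stop("window_size and step_size must be positive", call. = FALSE)
  if (length(positions) &&
      any(positions < span_start | positions >= span_end))
    stop("positions outside span", call. = FALSE)
  span_len <- span_end - span_start
  if (window_size > span_len) {
    warning("window_size exceeds span length; returning a single truncated window")
    starts <- span_start
    ends <- span_end
  } else {
    n_win <- floor((span_len - window_size) / step_size) + 1
    starts <- span_start + step_size * (seq_len(n_win) - 1)
    ends <- starts + window_size
    if (include_partial && max(ends) < span_end) {
      starts <- c(starts, max(starts) + step_size)
      ends <- c(ends, span_end)
    }
  }
  count_in <- function(p) vapply(seq_along(starts), function(i)
    sum(p >= starts[i] & p < ends[i]), numeric(1))
  out <- data.frame(window_start = starts, window_end = ends,
                    count = count_in(positions))
  if (!is.null(categories)) {
    stopifnot(length(categories) == length(positions))
    for (lev in sort(unique(categories)))
      out[[paste0("count_", lev)]] <- count_in(positions[categories == lev])
  }
  out
}
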