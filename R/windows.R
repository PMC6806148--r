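#' Build a sliding-window grid over a timespan
#'
#' Windows are timespan-defined, half-open intervals `[start, end)` of fixed
#' length laid out with a constant step `S = length_ms * (1 - overlap_frac)`.
#' Window `k` (0-based index) starts at `span_start + k * S`; only windows
#' ending at or before `span_end` are produced, so a span shorter than one
#' window yields an empty grid.
#'
#' @param span_start,span_end Span bounds in milliseconds, `span_end >
#'   span_start`.
#' @param length_ms Window length in milliseconds (default 1000).
#' @param overlap_frac Fractional overlap of consecutive windows in `[0, 1)`
#'   (e.g. 0.5 or 0.75).
#' @return A data frame (`window_grid`) with columns `index` (0-based),
#'   `start_ms`, `end_ms`.
#' @examples
#' make_window_grid(0, 10000, 1000, 0.5)   # 19 windows, step 500 ms
#' @export
make_window_grid <- function(span_start, span_end, length_ms = 1000,
                             overlap_frac = 0.5) {
  if (!is.finite(length_ms) || length_ms <= 0) {
    stop("length_ms must be positive")
  }
  if (!is.finite(overlap_frac) || overlap_frac < 0 || overlap_frac >= 1) {
    stop("overlap_frac must lie in [0, 1)")
  }
  if (span_end <= span_start) stop("span_end must exceed span_start")
  step <- length_ms * (1 - overlap_frac)
  span <- span_end - span_start
  if (span < length_ms) {
    return(empty_window_grid())
  }
  k_max <- floor((span - length_ms) / step)
  idx <- 0:k_max
  starts <- span_start + idx * step
  grid <- data.frame(index = idx, start_ms = starts,
                     end_ms = starts + length_ms)
  attr(grid, "step_ms") <- step
  attr(grid, "length_ms") <- length_ms
  class(grid) <- c("window_grid", "data.frame")
  grid
}

empty_window_grid <- function() {
  grid <- data.frame(index = integer(0), start_ms = numeric(0),
                     end_ms = numeric(0))
  class(grid) <- c("window_grid", "data.frame")
  grid
}

#' Samples of a stream falling inside a window
#'
#' Half-open assignment: a sample at time `t` belongs to the window when
#' `start_ms <= t < end_ms`, so a sample sitting exactly on a boundary of two
#' adjacent non-overlapping windows belongs to exactly one of them.
#'
#' @param window One-row portion of a [make_window_grid()] grid, or any list
#'   with `start_ms` and `end_ms`.
#' @param stream An [inertial_stream()].
#' @return Data frame of the samples inside the window, in time order.
#' @export
assign_samples <- function(window, stream) {
  idx <- window_sample_range(window$start_ms, window$end_ms,
                             stream$samples$t)
  stream$samples[idx, , drop = FALSE]
}

# Index range of sorted timestamps t with start <= t < end.
# Timestamps and bounds are in ms; the 0.5 shift makes the half-open
# comparison exact for integer-valued times.
window_sample_range <- function(start_ms, end_ms, t) {
  if (length(t) == 0L) return(integer(0))
  lo <- findInterval(start_ms - 0.5, t) + 1L
  hi <- findInterval(end_ms - 0.5, t)
  if (hi < lo) integer(0) else lo:hi
}

#' Match each vision window to its inertial window
#'
#' For a vision window starting at `ts`, the partner is the inertial window
#' with the smallest start `ts' >= ts` (the earliest inertial window starting
#' at or after the vision window). Vision windows with no such partner
#' (end-of-session) are unmatched.
#'
#' @param vision_grid,imu_grid Window grids from [make_window_grid()] (or any
#'   data frame with `start_ms`).
#' @return Integer vector, one element per vision window: the row number of
#'   the matched window in `imu_grid`, or `NA` if none exists.
#' @export
match_windows <- function(vision_grid, imu_grid) {
  if (nrow(imu_grid) == 0L) return(rep(NA_integer_, nrow(vision_grid)))
  ts <- vision_grid$start_ms
  p <- findInterval(ts, imu_grid$start_ms)  # starts <= ts
  exact <- p >= 1L & imu_grid$start_ms[pmax(p, 1L)] == ts
  pos <- ifelse(exact, p, p + 1L)
  pos[pos > nrow(imu_grid)] <- NA_integer_
  as.integer(pos)
}

#' De-overlap a window-indexed instance set
#'
#' Overlapping sliding windows share raw samples; with the vision grid's 50%
#' overlap every other window is kept, and with the inertial grid's 75%
#' overlap every fourth, so the retained windows are pairwise disjoint in
#' time and cross-validation folds cannot share data.
#'
#' @param index Integer vector of 0-based grid indices.
#' @param modality_mode `"vision_or_fused"` (keep even indices) or
#'   `"imu_only"` (keep indices divisible by 4).
#' @return Logical vector marking the retained elements.
#' @export
deoverlap_keep <- function(index,
                           modality_mode = c("vision_or_fused", "imu_only")) {
  modality_mode <- match.arg(modality_mode)
  divisor <- if (modality_mode == "vision_or_fused") 2L else 4L
  index %% divisor == 0L
}
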