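#' Detect the end of the initial stillness period
#'
#' Recording sessions start with a deliberate period of no movement so that
#' the moment motion begins can serve as a synchronization landmark across
#' devices. The detector takes the median acceleration magnitude over the
#' first `min_still_ms` of the stream as the resting baseline and returns the
#' timestamp of the first sample (at or after `min_still_ms` past the stream
#' start) whose magnitude deviates from that baseline by more than
#' `still_threshold` for 3 consecutive samples.
#'
#' @param stream An [inertial_stream()] (native clock).
#' @param still_threshold Magnitude deviation threshold in m/s^2 (default 1).
#' @param min_still_ms Minimum stillness duration in ms (default 1000).
#' @return Timestamp (ms, native clock) of motion onset.
#' @export
detect_motion_start <- function(stream, still_threshold = 1,
                                min_still_ms = 1000) {
  s <- stream$samples
  if (nrow(s) < 4L) stop("stream too short for motion detection")
  mag <- sqrt(s$x^2 + s$y^2 + s$z^2)
  t0 <- s$t[1L]
  prefix <- mag[s$t < t0 + min_still_ms]
  if (length(prefix) < 2L) {
    stop("no stillness prefix found; supply alignment offsets manually")
  }
  dev <- abs(mag - stats::median(prefix))
  exceed <- dev > still_threshold
  run3 <- exceed & c(exceed[-1L], FALSE) & c(exceed[-(1:2)], FALSE, FALSE)
  in_prefix <- s$t < t0 + min_still_ms
  # movement already inside the supposed stillness lead-in corrupts the
  # baseline (only meaningful for a positive threshold)
  if (still_threshold > 0 && any(run3 & in_prefix)) {
    stop("movement inside the stillness lead-in; ",
         "supply alignment offsets manually")
  }
  cand <- which(run3 & !in_prefix)
  if (length(cand) == 0L) {
    stop("no motion onset found (all-still stream); ",
         "supply alignment offsets manually")
  }
  s$t[cand[1L]]
}

#' Estimate per-device clock offsets from the stillness landmark
#'
#' Each device's motion onset is detected with [detect_motion_start()]; the
#' offset of a source is the shift (in ms, added to its native timestamps)
#' that makes its onset coincide with the reference source's. The reference
#' offset is 0 by construction.
#'
#' @param streams Named list of [inertial_stream()]s (native clocks).
#' @param reference Name of the reference source (default: first).
#' @param still_threshold,min_still_ms Passed to [detect_motion_start()].
#' @return An `alignment_offsets` data frame with columns `source`,
#'   `offset_ms`, and attribute `reference`.
#' @export
estimate_offsets <- function(streams, reference = names(streams)[1L],
                             still_threshold = 1, min_still_ms = 1000) {
  stopifnot(is.list(streams), !is.null(names(streams)),
            reference %in% names(streams))
  onsets <- vapply(streams, detect_motion_start, numeric(1),
                   still_threshold = still_threshold,
                   min_still_ms = min_still_ms)
  out <- data.frame(source = names(streams),
                    offset_ms = onsets[[reference]] - unname(onsets))
  alignment_offsets(out, reference)
}

#' Construct an alignment-offsets table
#'
#' @param offsets Data frame with columns `source`, `offset_ms`.
#' @param reference Name of the reference source; its offset must be 0.
#' @return An `alignment_offsets` data frame.
#' @export
alignment_offsets <- function(offsets, reference) {
  stopifnot(all(c("source", "offset_ms") %in% names(offsets)))
  if (!reference %in% offsets$source) {
    stop("reference source missing from offsets")
  }
  if (offsets$offset_ms[offsets$source == reference] != 0) {
    stop("reference source must have offset 0")
  }
  structure(offsets, reference = reference,
            class = c("alignment_offsets", "data.frame"))
}

#' Look up one source's offset
#' @param offsets An `alignment_offsets` table.
#' @param source Source name.
#' @return Offset in ms.
#' @export
offset_of <- function(offsets, source) {
  i <- match(source, offsets$source)
  if (is.na(i)) stop("unknown source: ", source)
  offsets$offset_ms[i]
}

#' Trim modalities to their common timespan
#'
#' All modalities are cut to the span they jointly cover: the latest start
#' and the earliest end among the per-source spans. Data outside this span is
#' discarded before windowing.
#'
#' @param spans List of length-2 numeric vectors `(start, end)`, or a 2-column
#'   matrix with one row per source.
#' @return Numeric `(start, end)` of the common span.
#' @export
trim_to_common_span <- function(spans) {
  if (is.matrix(spans)) spans <- asplit(spans, 1L)
  if (length(spans) == 0L) stop("at least one span required")
  starts <- vapply(spans, `[[`, numeric(1), 1L)
  ends <- vapply(spans, `[[`, numeric(1), 2L)
  lo <- max(starts)
  hi <- min(ends)
  if (lo >= hi) stop("no temporal overlap between sources")
  c(lo, hi)
}

# Timespan (start, end) covered by a stream / detection track.
stream_span <- function(stream) {
  t <- stream$samples$t
  c(t[1L], t[length(t)] + 1000 / stream$nominal_rate_hz)
}

track_span <- function(track, frame_period_ms = 40) {
  t <- track$frames$frame_t
  c(t[1L], t[length(t)] + frame_period_ms)
}
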