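#' Construct an inertial stream
#'
#' An inertial stream is a timestamped 3-axis acceleration series recorded by
#' one wrist-worn device. Timestamps are integer milliseconds on the device's
#' native clock (or, after alignment, on the unified session timeline) and
#' must be strictly increasing.
#'
#' @param t Numeric vector of timestamps in milliseconds, strictly increasing.
#' @param x,y,z Numeric vectors of acceleration in m/s^2, same length as `t`.
#' @param device_id Device identifier string.
#' @param position Sensor placement, `"left_wrist"` or `"right_wrist"`.
#' @param nominal_rate_hz Nominal sampling rate in Hz (default 50).
#' @return An object of class `inertial_stream`: a list with a `samples`
#'   data frame (`t`, `x`, `y`, `z`) plus device metadata.
#' @export
inertial_stream <- function(t, x, y, z, device_id = "unknown",
                            position = c("left_wrist", "right_wrist"),
                            nominal_rate_hz = 50) {
  position <- match.arg(position)
  t <- as.numeric(t)
  n <- length(t)
  if (length(x) != n || length(y) != n || length(z) != n) {
    stop("t, x, y, z must have equal length")
  }
  if (n > 0L) {
    if (any(!is.finite(t)) || any(!is.finite(x)) || any(!is.finite(y)) ||
        any(!is.finite(z))) {
      stop("inertial samples must be finite")
    }
    dt <- diff(t)
    if (any(dt == 0)) {
      stop("duplicate timestamps at positions: ",
           paste(utils::head(which(dt == 0) + 1L, 5L), collapse = ", "))
    }
    if (any(dt < 0)) {
      stop("timestamps must be strictly increasing (retrograde at position ",
           which(dt < 0)[1L] + 1L, ")")
    }
  }
  if (!is.numeric(nominal_rate_hz) || nominal_rate_hz <= 0) {
    stop("nominal_rate_hz must be positive")
  }
  structure(
    list(samples = data.frame(t = t, x = as.numeric(x), y = as.numeric(y),
                              z = as.numeric(z)),
         device_id = as.character(device_id), position = position,
         nominal_rate_hz = nominal_rate_hz),
    class = "inertial_stream")
}

#' @export
print.inertial_stream <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<inertial_stream> %s (%s), %d samples @ %g Hz nominal",
              x$device_id, x$position, n, x$nominal_rate_hz))
  if (n > 0L) {
    cat(sprintf(", t = [%g, %g] ms", x$samples$t[1L], x$samples$t[n]))
  }
  cat("\n")
  invisible(x)
}

#' Number of samples in an inertial stream
#' @param stream An `inertial_stream`.
#' @return Integer sample count.
#' @export
n_samples <- function(stream) nrow(stream$samples)

#' Shift a stream's timestamps onto another clock
#'
#' Adds `offset_ms` to every timestamp, e.g. to move a device's native clock
#' onto the unified session timeline.
#'
#' @param stream An `inertial_stream`.
#' @param offset_ms Signed shift in milliseconds.
#' @return The shifted stream.
#' @export
shift_stream <- function(stream, offset_ms) {
  stream$samples$t <- stream$samples$t + offset_ms
  stream
}

#' Construct a detection track
#'
#' A detection track holds per-frame object detections for one egocentric
#' video: the frame timeline (so frames with zero boxes are represented) and
#' a long table of class-labeled axis-aligned boxes with confidences. Pixel
#' coordinates have their origin at the top-left, `x_max > x_min`,
#' `y_max > y_min`, and box edges are treated as half-open pixel intervals.
#'
#' @param frames Data frame with columns `frame_index`, `frame_t`
#'   (milliseconds, strictly increasing).
#' @param boxes Data frame with columns `frame_index`, `class`, `confidence`,
#'   `x_min`, `y_min`, `x_max`, `y_max`. May have zero rows.
#' @return An object of class `detection_track`.
#' @export
detection_track <- function(frames, boxes) {
  need_f <- c("frame_index", "frame_t")
  need_b <- c("frame_index", "class", "confidence",
              "x_min", "y_min", "x_max", "y_max")
  if (!all(need_f %in% names(frames))) stop("frames needs columns: ",
                                            paste(need_f, collapse = ", "))
  if (!all(need_b %in% names(boxes))) stop("boxes needs columns: ",
                                           paste(need_b, collapse = ", "))
  frames <- frames[need_f]
  boxes <- boxes[need_b]
  if (nrow(frames) > 1L && any(diff(frames$frame_t) <= 0)) {
    stop("frame timestamps must be strictly increasing")
  }
  if (nrow(boxes) > 0L) {
    if (!all(boxes$frame_index %in% frames$frame_index)) {
      stop("boxes reference unknown frame_index values")
    }
    bad_conf <- boxes$confidence < 0 | boxes$confidence > 1
    if (any(bad_conf)) stop("box confidences must lie in [0, 1]")
    bad_box <- boxes$x_max <= boxes$x_min | boxes$y_max <= boxes$y_min
    if (any(bad_box)) stop("boxes must satisfy x_max > x_min and y_max > y_min")
  }
  boxes$class <- as.character(boxes$class)
  structure(list(frames = frames, boxes = boxes), class = "detection_track")
}

#' @export
print.detection_track <- function(x, ...) {
  cat(sprintf("<detection_track> %d frames, %d boxes, %d classes\n",
              nrow(x$frames), nrow(x$boxes),
              length(unique(x$boxes$class))))
  invisible(x)
}

#' Shift a detection track's frame timestamps
#' @param track A `detection_track`.
#' @param offset_ms Signed shift in milliseconds.
#' @return The shifted track.
#' @export
shift_track <- function(track, offset_ms) {
  track$frames$frame_t <- track$frames$frame_t + offset_ms
  track
}

#' Construct an annotation track
#'
#' Labeled activity intervals on the unified timeline. Intervals are half-open
#' `[start_ms, end_ms)` and may not overlap each other within one track.
#'
#' @param start_ms,end_ms Numeric vectors, interval bounds in milliseconds.
#' @param class Character vector of activity labels.
#' @param subject,session Identifiers for provenance.
#' @return An object of class `annotation_track` (a data frame).
#' @export
annotation_track <- function(start_ms, end_ms, class,
                             subject = "s1", session = "1") {
  n <- length(start_ms)
  if (length(end_ms) != n || length(class) != n) {
    stop("start_ms, end_ms, class must have equal length")
  }
  if (any(end_ms <= start_ms)) stop("intervals must satisfy end_ms > start_ms")
  df <- data.frame(start_ms = as.numeric(start_ms),
                   end_ms = as.numeric(end_ms),
                   class = as.character(class),
                   stringsAsFactors = FALSE)
  df <- df[order(df$start_ms), , drop = FALSE]
  rownames(df) <- NULL
  if (n > 1L && any(df$start_ms[-1L] < df$end_ms[-n])) {
    stop("annotation intervals overlap within one track")
  }
  structure(df, subject = as.character(subject),
            session = as.character(session),
            class = c("annotation_track", "data.frame"))
}
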