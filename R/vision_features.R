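#' @name vision-features
#' @title Hand-object interaction features from detection boxes
#'
#' @description
#' Per frame, the hand (detected as the `person` class by common pre-trained
#' detectors) is located and the fraction of every other object's bounding
#' box covered by the hand box is recorded, giving a vector of length
#' `|catalog| - 1`. Frames without a positive hand detection receive a
#' sentinel vector of -1. Frame vectors are then averaged over fixed-size
#' frame windows (default 10 frames with stride 5) to express sustained
#' interaction rather than a hand briefly passing over an object.
NULL

#' Select the hand box of a frame
#'
#' Among boxes of the hand class with confidence at or above `min_conf`, the
#' highest-confidence box wins; ties go to the larger area, then to the
#' smallest `x_min`.
#'
#' @param frame_boxes Data frame of one frame's boxes (columns `class`,
#'   `confidence`, `x_min`, `y_min`, `x_max`, `y_max`).
#' @param hand_class Class label of the hand detection (default `"person"`).
#' @param min_conf Minimum confidence (default 0.5).
#' @return One-row data frame, or `NULL` when no box qualifies.
#' @export
select_hand <- function(frame_boxes, hand_class = "person", min_conf = 0.5) {
  cand <- frame_boxes[frame_boxes$class == hand_class &
                        frame_boxes$confidence >= min_conf, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  area <- (cand$x_max - cand$x_min) * (cand$y_max - cand$y_min)
  ord <- order(-cand$confidence, -area, cand$x_min)
  cand[ord[1L], , drop = FALSE]
}

#' Fraction of an object box covered by the hand box
#'
#' Overlap is normalized by the object's area — `area(hand intersect object)
#' / area(object)` — so a hand fully covering a small object scores 1
#' regardless of the hand box size. Boxes are half-open pixel intervals;
#' disjoint boxes score 0.
#'
#' @param hand,obj One-row data frames (or lists) with `x_min`, `y_min`,
#'   `x_max`, `y_max`.
#' @param normalization `"object"` (default) or `"iou"` for intersection over
#'   union.
#' @return Overlap fraction in `[0, 1]`.
#' @export
box_overlap <- function(hand, obj, normalization = c("object", "iou")) {
  normalization <- match.arg(normalization)
  obj_area <- (obj$x_max - obj$x_min) * (obj$y_max - obj$y_min)
  if (!is.finite(obj_area) || obj_area <= 0) {
    warning("degenerate zero-area object box; overlap set to 0")
    return(0)
  }
  iw <- min(hand$x_max, obj$x_max) - max(hand$x_min, obj$x_min)
  ih <- min(hand$y_max, obj$y_max) - max(hand$y_min, obj$y_min)
  inter <- max(0, iw) * max(0, ih)
  if (normalization == "object") {
    inter / obj_area
  } else {
    hand_area <- (hand$x_max - hand$x_min) * (hand$y_max - hand$y_min)
    inter / (hand_area + obj_area - inter)
  }
}

#' Single-frame interaction vector
#'
#' @param frame_boxes Data frame of one frame's boxes.
#' @param catalog Ordered character vector of all detector classes, including
#'   the hand class; feature positions follow this order with the hand class
#'   removed.
#' @param hand_class,min_conf See [select_hand()].
#' @param normalization Overlap normalization, see [box_overlap()].
#' @return Named numeric vector of length `length(catalog) - 1`: all -1 when
#'   no hand is detected; otherwise, per class, the maximum overlap over that
#'   class's detected instances (0 when the class is absent from the frame).
#' @export
frame_feature <- function(frame_boxes, catalog, hand_class = "person",
                          min_conf = 0.5,
                          normalization = c("object", "iou")) {
  normalization <- match.arg(normalization)
  if (!hand_class %in% catalog) stop("catalog must contain hand_class")
  obj_classes <- setdiff(catalog, hand_class)
  hand <- select_hand(frame_boxes, hand_class, min_conf)
  if (is.null(hand)) {
    return(stats::setNames(rep(-1, length(obj_classes)), obj_classes))
  }
  out <- stats::setNames(rep(0, length(obj_classes)), obj_classes)
  keep <- frame_boxes$class != hand_class &
    frame_boxes$confidence >= min_conf &
    frame_boxes$class %in% obj_classes
  objs <- frame_boxes[keep, , drop = FALSE]
  for (i in seq_len(nrow(objs))) {
    cls <- objs$class[i]
    ov <- box_overlap(hand, objs[i, ], normalization)
    if (ov > out[[cls]]) out[[cls]] <- ov
  }
  out
}

# Per-frame feature matrix for a whole track (n_frames x (|catalog|-1)).
frame_feature_matrix <- function(track, catalog, hand_class = "person",
                                 min_conf = 0.5, normalization = "object") {
  obj_classes <- setdiff(catalog, hand_class)
  split_idx <- split(seq_len(nrow(track$boxes)), track$boxes$frame_index)
  out <- matrix(-1, nrow(track$frames), length(obj_classes),
                dimnames = list(NULL, obj_classes))
  for (i in seq_len(nrow(track$frames))) {
    fi <- as.character(track$frames$frame_index[i])
    fb <- track$boxes[split_idx[[fi]], , drop = FALSE]
    out[i, ] <- frame_feature(fb, catalog, hand_class, min_conf,
                              normalization)
  }
  out
}

#' Windowed interaction features for a detection track
#'
#' Consecutive single-frame vectors are averaged over windows of
#' `window_size` frames advanced by `stride` frames (defaults 10 and 5, i.e.
#' 50% overlap). Sentinel (-1) vectors of hand-less frames are included in
#' the mean by default; `sentinel_mode = "exclude"` instead averages only
#' hand-positive frames (renormalizing), falling back to -1 when a window has
#' none. Trailing partial windows are dropped. Each window's timespan is
#' `[first frame time, last frame time + frame_period_ms)` so vision windows
#' can be matched against inertial windows on the unified timeline.
#'
#' @param track A [detection_track()] on the unified timeline.
#' @param catalog Ordered class catalog including the hand class.
#' @param window_size,stride Frame counts (defaults 10 and 5).
#' @param frame_period_ms Nominal frame period in ms (default 40, i.e. 25
#'   fps).
#' @param hand_class,min_conf,normalization See [frame_feature()].
#' @param sentinel_mode `"include"` (default) or `"exclude"`.
#' @return List with `grid` (data frame `index`, `start_ms`, `end_ms`) and
#'   `features` (matrix, one row per window).
#' @export
window_vision_features <- function(track, catalog, window_size = 10L,
                                   stride = 5L, frame_period_ms = 40,
                                   hand_class = "person", min_conf = 0.5,
                                   normalization = c("object", "iou"),
                                   sentinel_mode = c("include", "exclude")) {
  normalization <- match.arg(normalization)
  sentinel_mode <- match.arg(sentinel_mode)
  if (window_size < 1L || stride < 1L) stop("window_size and stride must be >= 1")
  n <- nrow(track$frames)
  if (n < window_size) {
    return(list(grid = empty_window_grid(),
                features = matrix(numeric(0), 0L,
                                  length(catalog) - 1L,
                                  dimnames = list(NULL,
                                                  setdiff(catalog, hand_class)))))
  }
  fmat <- frame_feature_matrix(track, catalog, hand_class, min_conf,
                               normalization)
  n_win <- (n - window_size) %/% stride + 1L
  feats <- matrix(0, n_win, ncol(fmat), dimnames = list(NULL, colnames(fmat)))
  starts <- ends <- numeric(n_win)
  for (k in seq_len(n_win)) {
    rows <- ((k - 1L) * stride + 1L):((k - 1L) * stride + window_size)
    block <- fmat[rows, , drop = FALSE]
    if (sentinel_mode == "include") {
      feats[k, ] <- colMeans(block)
    } else {
      with_hand <- apply(block != -1, 1L, any)
      if (!any(with_hand)) {
        feats[k, ] <- -1
      } else {
        feats[k, ] <- colMeans(block[with_hand, , drop = FALSE])
      }
    }
    starts[k] <- track$frames$frame_t[rows[1L]]
    ends[k] <- track$frames$frame_t[rows[window_size]] + frame_period_ms
  }
  grid <- data.frame(index = seq_len(n_win) - 1L, start_ms = starts,
                     end_ms = ends)
  class(grid) <- c("window_grid", "data.frame")
  list(grid = grid, features = feats)
}
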