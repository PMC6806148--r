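box <- function(x0, y0, x1, y1, class = "obj", conf = 0.9) {
  data.frame(class = class, confidence = conf, x_min = x0, y_min = y0,
             x_max = x1, y_max = y1)
}

test_that("hand selection: argmax confidence, threshold, tie-breaks", {
  none <- box(0, 0, 10, 10, "cup")
  expect_null(select_hand(none))

  two <- rbind(box(0, 0, 10, 10, "person", 0.9),
               box(20, 0, 30, 10, "person", 0.6))
  expect_equal(select_hand(two)$x_min, 0)

  low <- box(0, 0, 10, 10, "person", 0.4)
  expect_null(select_hand(low, min_conf = 0.5))

  # equal confidence: larger area wins, then lower x_min
  tie <- rbind(box(5, 0, 10, 10, "person", 0.8),
               box(0, 0, 20, 20, "person", 0.8))
  expect_equal(select_hand(tie)$x_max, 20)
})

test_that("overlap is intersection over object area", {
  a <- box(0, 0, 10, 10)
  expect_equal(box_overlap(a, a), 1.0)
  expect_equal(box_overlap(a, box(50, 50, 60, 60)), 0.0)
  expect_equal(box_overlap(box(0, 0, 10, 10), box(5, 0, 15, 10)), 0.5)
  # iou alternative
  expect_equal(box_overlap(a, a, normalization = "iou"), 1.0)
  expect_equal(box_overlap(box(0, 0, 10, 10), box(5, 0, 15, 10), "iou"),
               50 / 150)
})

test_that("overlap matches the pixel-rasterization oracle", {
  set.seed(21)
  for (i in 1:200) {
    hand <- random_box()
    obj <- random_box()
    tol <- 1 / ((obj$x_max - obj$x_min) * (obj$y_max - obj$y_min))
    expect_equal(box_overlap(hand, obj), oracle_overlap_raster(hand, obj),
                 tolerance = tol)
  }
})

test_that("frame vectors use sentinels, zeros and the max-instance rule", {
  catalog <- c("person", paste0("c", 1:14))
  handless <- box(0, 0, 5, 5, "c1")
  expect_equal(unname(frame_feature(handless, catalog)), rep(-1, 14))

  hand_only <- box(0, 0, 100, 100, "person")
  expect_equal(unname(frame_feature(hand_only, catalog)), rep(0, 14))

  two_cups <- rbind(box(0, 0, 100, 100, "person"),
                    box(80, 0, 180, 100, "c3"),   # overlap 0.2
                    box(40, 0, 140, 100, "c3"))   # overlap 0.6
  f <- frame_feature(two_cups, catalog)
  expect_equal(f[["c3"]], 0.6)
  expect_equal(sum(f != 0), 1L)

  # low-confidence objects are ignored
  faint <- rbind(box(0, 0, 100, 100, "person"),
                 box(0, 0, 50, 50, "c2", conf = 0.3))
  expect_equal(frame_feature(faint, catalog)[["c2"]], 0)
})

test_that("windowed means include sentinels and follow the frame grid", {
  catalog <- c("person", "cup")
  mk_track <- function(feats_present) {
    nf <- length(feats_present)
    frames <- data.frame(frame_index = 0:(nf - 1),
                         frame_t = (0:(nf - 1)) * 40)
    boxes <- do.call(rbind, lapply(which(feats_present), function(i) {
      rbind(cbind(frame_index = i - 1, box(0, 0, 100, 100, "person")),
            cbind(frame_index = i - 1, box(0, 0, 50, 50, "cup")))
    }))
    if (is.null(boxes)) boxes <- cbind(frame_index = integer(0),
                                       box(0, 0, 1, 1)[0, ])
    detection_track(frames, boxes)
  }

  # 10 identical frames -> the common vector
  all10 <- mk_track(rep(TRUE, 10))
  w <- window_vision_features(all10, catalog)
  expect_equal(nrow(w$features), 1L)
  expect_equal(unname(w$features[1, "cup"]), 1.0)
  expect_equal(w$grid$start_ms, 0)
  expect_equal(w$grid$end_ms, 9 * 40 + 40)

  # 5 hand frames at overlap 1 + 5 hand-less -> (5 - 5)/10 = 0
  half <- mk_track(c(rep(TRUE, 5), rep(FALSE, 5)))
  expect_equal(unname(window_vision_features(half, catalog)$features[1, "cup"]), 0)
  # exclude mode averages only the hand-positive frames
  expect_equal(unname(window_vision_features(half, catalog,
                                             sentinel_mode = "exclude")$features[1, "cup"]),
               1)

  # 25 frames, size 10, stride 5 -> 4 windows starting at frames 0,5,10,15
  t25 <- mk_track(rep(TRUE, 25))
  w25 <- window_vision_features(t25, catalog)
  expect_equal(nrow(w25$grid), 4L)
  expect_equal(w25$grid$start_ms, c(0, 5, 10, 15) * 40)

  # fewer frames than a window -> empty
  expect_equal(nrow(window_vision_features(mk_track(rep(TRUE, 7)),
                                           catalog)$grid), 0L)
})

test_that("window values stay in [-1,1]; -1 only for all-handless windows", {
  set.seed(31)
  catalog <- c("person", "a", "b")
  for (rep in 1:20) {
    nf <- 20
    frames <- data.frame(frame_index = 0:(nf - 1), frame_t = (0:(nf - 1)) * 40)
    boxes <- do.call(rbind, lapply(0:(nf - 1), function(fi) {
      out <- NULL
      if (runif(1) < 0.6) {
        out <- cbind(frame_index = fi, box(0, 0, 100, 100, "person"))
        if (runif(1) < 0.7) {
          x0 <- runif(1, 0, 150)
          out <- rbind(out, cbind(frame_index = fi,
                                  box(x0, 0, x0 + 50, 50, sample(c("a", "b"), 1))))
        }
      }
      out
    }))
    if (is.null(boxes)) next
    track <- detection_track(frames, boxes)
    w <- window_vision_features(track, catalog)
    expect_true(all(w$features >= -1 & w$features <= 1))
    fm <- actifuse:::frame_feature_matrix(track, catalog)
    for (k in seq_len(nrow(w$grid))) {
      rows <- (k - 1) * 5 + 1:10
      # oracle: recompute the mean per window from per-frame vectors
      expect_equal(unname(w$features[k, ]), unname(colMeans(fm[rows, ])),
                   tolerance = 1e-12)
      all_handless <- all(fm[rows, ] == -1)
      expect_equal(all(w$features[k, ] == -1), all_handless)
    }
  }
})

test_that("enlarging an object's intersection never lowers its window value", {
  catalog <- c("person", "cup")
  val <- function(shift) {
    frames <- data.frame(frame_index = 0:9, frame_t = (0:9) * 40)
    boxes <- do.call(rbind, lapply(0:9, function(fi) {
      rbind(cbind(frame_index = fi, box(0, 0, 100, 100, "person")),
            cbind(frame_index = fi, box(shift, 0, shift + 100, 100, "cup")))
    }))
    window_vision_features(detection_track(frames, boxes),
                           catalog)$features[1, "cup"]
  }
  vals <- vapply(seq(150, 0, by = -25), val, numeric(1))
  expect_true(all(diff(vals) >= 0))
})
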