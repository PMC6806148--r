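#' @name synthetic-data
#' @title Synthetic multimodal ADL scenario generator
#'
#' @description
#' Generates multi-subject recording sessions that emulate the structure of
#' two-wrist 50 Hz accelerometer traces plus a 25 fps egocentric detection
#' stream: a stillness lead-in before any motion (the cross-device
#' synchronization landmark), interleaved activity intervals following fixed
#' sequences, class-specific sum-of-sinusoid motion templates per wrist,
#' class-specific hand-object overlap patterns drawn from Beta laws and
#' realized geometrically as boxes, detector noise (missed hands, false
#' positives, box jitter, confidence spread), white accelerometer noise, and
#' per-device clock offsets. Every draw is seed-controlled, so the generator
#' doubles as the test bed for each pipeline stage.
NULL

#' Default detector class catalog
#'
#' The hand is detected as `"person"`, the convention of detectors pre-trained
#' on common object-detection corpora; the remaining entries are household
#' objects. Feature vectors have length `length(catalog) - 1`.
#'
#' @return Character vector of class names, hand class first.
#' @export
default_catalog <- function() {
  c("person", "glass", "pillbox", "bread", "knife", "napkin",
    "banana", "plate", "cup", "spoon", "table")
}

default_sequences <- function() {
  list(c("take_snack", "take_meds", "drink_water", "take_snack",
         "wipe_mouth"),
       c("prepare_bread", "eat_bread", "take_meds", "drink_water",
         "eat_bread", "wipe_mouth"))
}

# Deterministic per-class motion template: one sinusoid per axis per wrist.
# Cosine phase (pi/2) gives the abrupt onset that follows the deliberate
# stillness pause; the z amplitude is kept >= 2.5 m/s^2 so motion onsets are
# visible in the acceleration magnitude.
default_motion_templates <- function(classes) {
  out <- list()
  for (i in seq_along(classes)) {
    tpl <- lapply(1:2, function(w) {
      f0 <- 0.6 + 0.35 * i + 0.1 * (w - 1)
      list(amp = c(1.2 + 0.4 * ((i + w) %% 3),
                   1.0 + 0.3 * ((i + 2 * w) %% 3),
                   2.5 + 0.3 * i),
           freq = f0 * c(1, 1.5, 0.75),
           phase = rep(pi / 2, 3))
    })
    out[[classes[i]]] <- list(left = tpl[[1]], right = tpl[[2]])
  }
  out
}

# Each class interacts with one signature object; overlap ~ Beta(8, 2).
default_object_models <- function(classes, catalog, hand_class = "person") {
  objects <- setdiff(catalog, hand_class)
  out <- list()
  for (i in seq_along(classes)) {
    out[[classes[i]]] <- list(objects = objects[(i - 1L) %% length(objects) + 1L],
                              beta = c(8, 2))
  }
  out
}

#' Scenario configuration
#'
#' Collects every knob of the synthetic generator with realistic defaults:
#' two subjects with six sessions each, the two interleaved ADL sequences
#' (snack-meds-drink-snack-wipe and prepare-eat-meds-drink-eat-wipe), 50 Hz
#' inertial sampling, 25 fps frames, a 3 s stillness lead-in, short
#' interruptions between activities, and mild sensor/detector noise.
#'
#' @param subjects Number of subjects (default 2).
#' @param sessions_per_subject Sessions per subject (default 6).
#' @param activity_sequences List of activity-label sequences; sessions
#'   alternate between them.
#' @param duration_range_ms Per-activity duration range (default 3000-5000).
#' @param gap_mode `"interrupted"` (short pauses between activities, default)
#'   or `"natural"` (back-to-back).
#' @param gap_range_ms Pause duration range for `"interrupted"`.
#' @param imu_rate_hz Inertial sampling rate (default 50).
#' @param fps Frame rate (default 25).
#' @param stillness_lead_ms Stillness before the first activity (default
#'   3000).
#' @param trailing_still_ms Stillness after the last activity (default 1000).
#' @param offsets_ms Named per-source clock offsets in ms (added to a
#'   source's native timestamps to reach the unified timeline); default all 0.
#' @param motion_templates Per-class, per-wrist sum-of-sinusoid parameters
#'   (`amp`, `freq`, `phase` per axis; matrices stack harmonics). Defaults
#'   are distinct per class.
#' @param object_models Per-class list of visible object classes and
#'   Beta(shape1, shape2) overlap law.
#' @param catalog Detector class catalog, hand class included.
#' @param hand_class Hand label in the catalog (default `"person"`).
#' @param detector List: `miss_prob` (hand missed per frame), `fp_rate`
#'   (false-positive box per frame), `jitter_px` (box jitter sd),
#'   `confidence_range`.
#' @param hand_presence_idle Probability a hand is detected in a frame
#'   outside activities (default 0.7).
#' @param accel_noise_sd White accelerometer noise sd in m/s^2 (default 0.3).
#' @param seed Integer seed (mandatory).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(subjects = 2L, sessions_per_subject = 6L,
                            activity_sequences = default_sequences(),
                            duration_range_ms = c(3000, 5000),
                            gap_mode = c("interrupted", "natural"),
                            gap_range_ms = c(1000, 2000),
                            imu_rate_hz = 50, fps = 25,
                            stillness_lead_ms = 3000,
                            trailing_still_ms = 1000,
                            offsets_ms = c(left_wrist = 0, right_wrist = 0,
                                           camera = 0),
                            motion_templates = NULL, object_models = NULL,
                            catalog = default_catalog(),
                            hand_class = "person",
                            detector = list(miss_prob = 0.05, fp_rate = 0.05,
                                            jitter_px = 0,
                                            confidence_range = c(0.6, 0.95)),
                            hand_presence_idle = 0.7,
                            accel_noise_sd = 0.3, seed) {
  if (missing(seed)) stop("seed is mandatory")
  gap_mode <- match.arg(gap_mode)
  if (subjects < 1L) stop("subjects must be >= 1")
  if (sessions_per_subject < 1L) stop("sessions_per_subject must be >= 1")
  if (imu_rate_hz <= 0 || fps <= 0) stop("rates must be positive")
  if (any(duration_range_ms <= 0) ||
      duration_range_ms[2] < duration_range_ms[1]) {
    stop("invalid duration_range_ms")
  }
  if (detector$miss_prob < 0 || detector$miss_prob > 1 ||
      detector$fp_rate < 0 || detector$fp_rate > 1) {
    stop("detector probabilities must lie in [0, 1]")
  }
  if (accel_noise_sd < 0) stop("accel_noise_sd must be >= 0")
  classes <- unique(unlist(activity_sequences))
  if (!hand_class %in% catalog) stop("catalog must contain hand_class")
  if (is.null(motion_templates)) {
    motion_templates <- default_motion_templates(classes)
  }
  if (is.null(object_models)) {
    object_models <- default_object_models(classes, catalog, hand_class)
  }
  missing_tpl <- setdiff(classes, names(motion_templates))
  if (length(missing_tpl) > 0L) {
    stop("motion templates missing for: ", paste(missing_tpl, collapse = ", "))
  }
  missing_obj <- setdiff(classes, names(object_models))
  if (length(missing_obj) > 0L) {
    stop("object models missing for: ", paste(missing_obj, collapse = ", "))
  }
  structure(
    list(subjects = as.integer(subjects),
         sessions_per_subject = as.integer(sessions_per_subject),
         activity_sequences = activity_sequences, classes = classes,
         duration_range_ms = duration_range_ms, gap_mode = gap_mode,
         gap_range_ms = gap_range_ms, imu_rate_hz = imu_rate_hz, fps = fps,
         stillness_lead_ms = stillness_lead_ms,
         trailing_still_ms = trailing_still_ms, offsets_ms = offsets_ms,
         motion_templates = motion_templates, object_models = object_models,
         catalog = catalog, hand_class = hand_class, detector = detector,
         hand_presence_idle = hand_presence_idle,
         accel_noise_sd = accel_noise_sd, seed = as.integer(seed)),
    class = "scenario_config")
}

#' Confusable four-class design
#'
#' Rewrites a configuration so that its first two classes share an identical
#' motion template but interact with disjoint objects (inertial data alone
#' cannot separate them), while its third and fourth classes share the same
#' object but keep distinct motion templates (vision alone cannot separate
#' them). This is the canonical setting where fusing both modalities must
#' beat each single modality.
#'
#' @param config A [scenario_config()] with at least 4 activity classes.
#' @return The modified `scenario_config` (sequences restricted to the four
#'   confusable classes).
#' @export
make_confusable_design <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (length(config$classes) < 4L) {
    stop("confusable design needs at least 4 activity classes")
  }
  cls <- config$classes[1:4]
  objs <- setdiff(config$catalog, config$hand_class)
  if (length(objs) < 3L) stop("catalog needs at least 3 object classes")
  config$motion_templates[[cls[2]]] <- config$motion_templates[[cls[1]]]
  config$object_models[[cls[1]]]$objects <- objs[1L]
  config$object_models[[cls[2]]]$objects <- objs[2L]
  config$object_models[[cls[3]]]$objects <- objs[3L]
  config$object_models[[cls[4]]]$objects <- objs[3L]
  config$object_models[[cls[4]]]$beta <- config$object_models[[cls[3]]]$beta
  config$activity_sequences <- list(cls, cls[c(3L, 1L, 4L, 2L)])
  config$classes <- cls
  config
}

#' Canonical confusable validation scenarios
#'
#' Two fixed study conditions built on [make_confusable_design()] with 2
#' subjects and 6 sessions each:
#'
#' * `confusable_noise_free_config()` switches every stochastic nuisance off
#'   — no accelerometer noise, no missed hands (and a hand in every idle
#'   frame), no false positives, no jitter, overlap degenerate at 1 — and
#'   fixes the stillness lead (3200 ms), activity durations (4000 ms) and
#'   pauses (1600 ms) to multiples of the 400 ms vision window span. Every
#'   interval boundary then coincides with an even-index window start, so
#'   after de-overlapping no retained window straddles a boundary, and the
#'   whole session-to-features map is deterministic. Under this condition an
#'   end-to-end run must recover the labels perfectly.
#' * `confusable_moderate_noise_config()` keeps the confusable structure but
#'   with realistic nuisance levels (accelerometer sd 1 m/s^2, 20% missed
#'   hands, 10% false positives, 15 px jitter, Beta(8, 2) overlaps). This is
#'   the condition under which late fusion must beat each single modality.
#'
#' @param seed Integer seed.
#' @return A `scenario_config`.
#' @export
confusable_noise_free_config <- function(seed) {
  cfg <- scenario_config(
    duration_range_ms = c(4000, 4000), gap_range_ms = c(1600, 1600),
    stillness_lead_ms = 3200, accel_noise_sd = 0,
    detector = list(miss_prob = 0, fp_rate = 0, jitter_px = 0,
                    confidence_range = c(0.9, 0.9)),
    hand_presence_idle = 1, seed = seed)
  cfg <- make_confusable_design(cfg)
  for (cl in names(cfg$object_models)) {
    cfg$object_models[[cl]]$beta <- c(1, 0)  # point mass at overlap 1
  }
  cfg
}

#' @rdname confusable_noise_free_config
#' @export
confusable_moderate_noise_config <- function(seed) {
  cfg <- scenario_config(
    accel_noise_sd = 1,
    detector = list(miss_prob = 0.2, fp_rate = 0.1, jitter_px = 15,
                    confidence_range = c(0.5, 0.95)),
    seed = seed)
  make_confusable_design(cfg)
}

# Beta(shape1, shape2) overlap draw; a zero shape degenerates to a point
# mass (shape2 = 0 -> always 1, shape1 = 0 -> always 0) so noise-free
# scenarios are exactly deterministic.
draw_overlap <- function(beta) {
  if (beta[2] == 0) return(1)
  if (beta[1] == 0) return(0)
  stats::rbeta(1, beta[1], beta[2])
}

eval_template <- function(tpl, t_rel_ms) {
  # sum-of-sinusoids per axis; amp/freq/phase are 3-vectors or k x 3 matrices
  amp <- rbind(tpl$amp); freq <- rbind(tpl$freq); phase <- rbind(tpl$phase)
  out <- matrix(0, length(t_rel_ms), 3L)
  for (h in seq_len(nrow(amp))) {
    for (a in 1:3) {
      out[, a] <- out[, a] +
        amp[h, a] * sin(2 * pi * freq[h, a] * t_rel_ms / 1000 + phase[h, a])
    }
  }
  out
}

session_seed <- function(config, subject_idx, session_idx) {
  (config$seed %% 100000L) * 101L + subject_idx * 1009L + session_idx
}

#' Generate one synthetic session
#'
#' Produces the two wrist streams (native clocks), the detection track
#' (native camera clock), the annotation track (unified timeline) and the
#' true per-source offsets. Streams begin with `stillness_lead_ms` of
#' gravity-plus-noise; each activity interval superimposes its wrist-specific
#' motion template and draws per-frame boxes whose hand-object overlap equals
#' the value drawn from the class's Beta law (before optional jitter).
#'
#' @param config A [scenario_config()].
#' @param subject_idx,session_idx 1-based indices; they determine the
#'   session-local seed, so regeneration is reproducible.
#' @return List with elements `streams` (named list `left_wrist`,
#'   `right_wrist`), `detections`, `annotations`, `true_offsets` (data frame
#'   `source`, `offset_ms`), `subject`, `session`.
#' @export
generate_session <- function(config, subject_idx = 1L, session_idx = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(session_seed(config, subject_idx, session_idx))
  seqs <- config$activity_sequences
  sequence <- seqs[[(session_idx - 1L) %% length(seqs) + 1L]]
  dr <- config$duration_range_ms
  gr <- config$gap_range_ms

  cur <- config$stillness_lead_ms
  starts <- ends <- numeric(length(sequence))
  for (i in seq_along(sequence)) {
    dur <- round(stats::runif(1, dr[1], dr[2]))
    starts[i] <- cur
    ends[i] <- cur + dur
    gap <- if (config$gap_mode == "interrupted")
      round(stats::runif(1, gr[1], gr[2])) else 0
    cur <- cur + dur + gap
  }
  t_end <- cur + config$trailing_still_ms
  ann <- annotation_track(starts, ends, sequence,
                          subject = paste0("subject", subject_idx),
                          session = as.character(session_idx))

  imu_step <- 1000 / config$imu_rate_hz
  t_imu <- seq(0, t_end, by = imu_step)
  streams <- list()
  for (wrist in c("left_wrist", "right_wrist")) {
    acc <- matrix(rep(c(0, 0, 9.81), each = length(t_imu)), ncol = 3L)
    for (i in seq_along(sequence)) {
      tpl <- config$motion_templates[[sequence[i]]][[
        if (wrist == "left_wrist") "left" else "right"]]
      in_act <- t_imu >= starts[i] & t_imu < ends[i]
      if (any(in_act)) {
        acc[in_act, ] <- acc[in_act, ] +
          eval_template(tpl, t_imu[in_act] - starts[i])
      }
    }
    if (config$accel_noise_sd > 0) {
      acc <- acc + matrix(stats::rnorm(length(acc), 0, config$accel_noise_sd),
                          ncol = 3L)
    }
    off <- offset_lookup(config$offsets_ms, wrist)
    streams[[wrist]] <- inertial_stream(
      t_imu - off, acc[, 1L], acc[, 2L], acc[, 3L],
      device_id = paste0("watch_", wrist), position = wrist,
      nominal_rate_hz = config$imu_rate_hz)
  }

  det <- generate_detections(config, starts, ends, sequence, t_end)
  det$frames$frame_t <- det$frames$frame_t -
    offset_lookup(config$offsets_ms, "camera")

  list(streams = streams, detections = det, annotations = ann,
       true_offsets = data.frame(source = names(config$offsets_ms),
                                 offset_ms = as.numeric(config$offsets_ms)),
       subject = paste0("subject", subject_idx),
       session = as.character(session_idx))
}

offset_lookup <- function(offsets_ms, source) {
  if (source %in% names(offsets_ms)) as.numeric(offsets_ms[[source]]) else 0
}

# Hand box is fixed; the object box (100 px square) is slid horizontally so
# that intersection / object-area equals the drawn overlap exactly, then
# jittered. Frame timestamps are on the unified timeline here; the caller
# shifts them to the camera's native clock.
generate_detections <- function(config, starts, ends, sequence, t_end) {
  period <- 1000 / config$fps
  t_f <- seq(0, t_end - period, by = period)
  nf <- length(t_f)
  hand <- c(x_min = 860, y_min = 540, x_max = 1060, y_max = 740)
  obj_size <- 100
  cr <- config$detector$confidence_range
  objs_pool <- setdiff(config$catalog, config$hand_class)

  rows <- list()
  n_row <- 0L
  add_box <- function(fi, cls, conf, x0, y0, x1, y1) {
    n_row <<- n_row + 1L
    rows[[n_row]] <<- list(fi, cls, conf, x0, y0, x1, y1)
  }
  for (i in seq_len(nf)) {
    t <- t_f[i]
    act <- which(starts <= t & t < ends)
    active <- length(act) > 0L
    hand_p <- if (active) 1 - config$detector$miss_prob else
      config$hand_presence_idle
    hand_here <- stats::runif(1) < hand_p
    if (hand_here) {
      add_box(i - 1L, config$hand_class, stats::runif(1, cr[1], cr[2]),
              hand[1], hand[2], hand[3], hand[4])
      if (active) {
        model <- config$object_models[[sequence[act[1L]]]]
        for (obj in model$objects) {
          v <- draw_overlap(model$beta)
          x0 <- hand[["x_max"]] - obj_size * v
          y0 <- hand[["y_min"]] + 40
          if (config$detector$jitter_px > 0) {
            d <- round(stats::rnorm(2, 0, config$detector$jitter_px))
            x0 <- x0 + d[1]; y0 <- y0 + d[2]
          }
          add_box(i - 1L, obj, stats::runif(1, cr[1], cr[2]),
                  x0, y0, x0 + obj_size, y0 + obj_size)
        }
      }
    }
    if (stats::runif(1) < config$detector$fp_rate) {
      cls <- sample(objs_pool, 1L)
      x0 <- stats::runif(1, 0, 1920 - obj_size)
      y0 <- stats::runif(1, 0, 1080 - obj_size)
      add_box(i - 1L, cls, stats::runif(1, cr[1], cr[2]),
              x0, y0, x0 + obj_size, y0 + obj_size)
    }
  }
  boxes <- if (n_row == 0L) {
    data.frame(frame_index = integer(0), class = character(0),
               confidence = numeric(0), x_min = numeric(0),
               y_min = numeric(0), x_max = numeric(0), y_max = numeric(0))
  } else {
    data.frame(frame_index = vapply(rows, `[[`, numeric(1), 1L),
               class = vapply(rows, `[[`, character(1), 2L),
               confidence = vapply(rows, `[[`, numeric(1), 3L),
               x_min = vapply(rows, `[[`, numeric(1), 4L),
               y_min = vapply(rows, `[[`, numeric(1), 5L),
               x_max = vapply(rows, `[[`, numeric(1), 6L),
               y_max = vapply(rows, `[[`, numeric(1), 7L))
  }
  detection_track(data.frame(frame_index = seq_len(nf) - 1L, frame_t = t_f),
                  boxes)
}

#' Generate a full cohort
#'
#' All `subjects x sessions_per_subject` sessions of a configuration,
#' in-memory. Use [write_cohort()] to materialize the on-disk dataset with
#' its manifest.
#'
#' @param config A [scenario_config()].
#' @return A `cohort`: list of sessions (see [generate_session()]) with the
#'   config attached as an attribute.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  sessions <- list()
  for (s in seq_len(config$subjects)) {
    for (k in seq_len(config$sessions_per_subject)) {
      sessions[[length(sessions) + 1L]] <- generate_session(config, s, k)
    }
  }
  structure(sessions, config = config, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<cohort> %d sessions (%d subjects x %d), classes: %s\n",
              length(x), cfg$subjects, cfg$sessions_per_subject,
              paste(cfg$classes, collapse = ", ")))
  invisible(x)
}
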