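#' Build fused instances for one session
#'
#' Runs the per-session half of the pipeline: shift every source onto the
#' unified timeline, trim to the common span, window and featurize both
#' modalities, match each vision window to the earliest inertial window
#' starting at or after it, and label windows from the annotation track.
#' Vision windows that lose their inertial partner (end of session, or the
#' partner was invalid in either stream) are dropped.
#'
#' @param session A session as produced by [generate_session()] /
#'   [read_cohort()].
#' @param catalog Detector class catalog.
#' @param window_length_ms,imu_overlap Inertial grid parameters (defaults
#'   1000 ms, 0.75).
#' @param vision_window_size,vision_stride Vision frame-window parameters
#'   (defaults 10, 5).
#' @param hand_class,min_conf,normalization,sentinel_mode Vision feature
#'   options, see [window_vision_features()].
#' @param min_cover Window labeling threshold, see [label_windows()].
#' @param min_samples Minimum samples per inertial window.
#' @param fps Camera frame rate, used for the nominal frame period
#'   (default 25).
#' @param align `"offsets"` (default; apply the session's offsets table) or
#'   `"stillness"` (re-estimate wrist offsets from the stillness landmark,
#'   keeping the camera offset from the table).
#' @param modality `"fused"` (default) or `"imu"` (inertial-grid instances
#'   only, no vision block).
#' @return A [fused_instances()] set for the session.
#' @export
build_instances <- function(session, catalog,
                            window_length_ms = 1000, imu_overlap = 0.75,
                            vision_window_size = 10L, vision_stride = 5L,
                            hand_class = "person", min_conf = 0.5,
                            normalization = "object",
                            sentinel_mode = "include",
                            min_cover = 0.5, min_samples = 4L, fps = 25,
                            align = c("offsets", "stillness"),
                            modality = c("fused", "imu")) {
  align <- match.arg(align)
  modality <- match.arg(modality)
  offs <- session$true_offsets
  if (align == "stillness") {
    est <- estimate_offsets(session$streams, reference = "left_wrist")
    offs$offset_ms[match(est$source, offs$source)] <- est$offset_ms +
      offs$offset_ms[offs$source == "left_wrist"]
  }
  left <- shift_stream(session$streams$left_wrist,
                       offs$offset_ms[offs$source == "left_wrist"])
  right <- shift_stream(session$streams$right_wrist,
                        offs$offset_ms[offs$source == "right_wrist"])
  frame_period <- 1000 / fps
  det <- shift_track(session$detections,
                     offs$offset_ms[offs$source == "camera"])

  span <- trim_to_common_span(list(stream_span(left), stream_span(right),
                                   track_span(det, frame_period)))
  keep_f <- det$frames$frame_t >= span[1L] &
    det$frames$frame_t + frame_period <= span[2L]
  det$frames <- det$frames[keep_f, , drop = FALSE]
  det$boxes <- det$boxes[det$boxes$frame_index %in% det$frames$frame_index, ,
                         drop = FALSE]

  imu_grid <- make_window_grid(span[1L], span[2L], window_length_ms,
                               imu_overlap)
  if (modality == "imu") {
    feats <- extract_imu_features(left, right, imu_grid, min_samples)
    labels <- label_windows(feats$grid, session$annotations, min_cover)
    meta <- data.frame(subject = session$subject, session = session$session,
                       index = feats$grid$index,
                       start_ms = feats$grid$start_ms,
                       end_ms = feats$grid$end_ms, label = labels)
    return(fused_instances(meta, imu = feats$features))
  }

  imu_feats <- extract_imu_features(left, right, imu_grid, min_samples)
  vis <- window_vision_features(det, catalog, vision_window_size,
                                vision_stride, frame_period, hand_class,
                                min_conf, normalization, sentinel_mode)
  pos <- match_windows(vis$grid, imu_grid)
  valid_row <- match(imu_grid$index[pos], imu_feats$grid$index)
  keep <- !is.na(pos) & !is.na(valid_row)
  labels <- label_windows(vis$grid, session$annotations, min_cover)
  meta <- data.frame(subject = session$subject, session = session$session,
                     index = vis$grid$index[keep],
                     start_ms = vis$grid$start_ms[keep],
                     end_ms = vis$grid$end_ms[keep],
                     imu_start_ms = imu_feats$grid$start_ms[valid_row[keep]],
                     label = labels[keep])
  fused_instances(meta, imu = imu_feats$features[valid_row[keep], ,
                                                 drop = FALSE],
                  vision = vis$features[keep, , drop = FALSE])
}

#' Build the de-overlapped instance table of a whole cohort
#'
#' @param cohort A [generate_cohort()] / [read_cohort()] result.
#' @param catalog Class catalog; defaults to the cohort's own.
#' @param modality `"fused"` or `"imu"`.
#' @param deoverlap Apply [deoverlap_subsample()] (default `TRUE`).
#' @param ... Passed to [build_instances()].
#' @return A [fused_instances()] set across all sessions.
#' @export
cohort_instances <- function(cohort, catalog = NULL,
                             modality = c("fused", "imu"),
                             deoverlap = TRUE, ...) {
  modality <- match.arg(modality)
  if (is.null(catalog)) {
    config <- attr(cohort, "config")
    catalog <- if (!is.null(config)) config$catalog else attr(cohort, "catalog")
  }
  if (is.null(catalog)) stop("catalog required")
  sets <- lapply(cohort, build_instances, catalog = catalog,
                 modality = modality, ...)
  out <- bind_instances(sets)
  if (deoverlap) {
    out <- deoverlap_subsample(out, if (modality == "fused")
      "vision_or_fused" else "imu_only")
  }
  out
}

#' Run the full pipeline from a configuration
#'
#' Executes generate/load -> align -> extract -> match -> fuse -> evaluate
#' and optionally writes the report (CSV + JSON) and a run log with the
#' resolved configuration. Reruns with an identical configuration reproduce
#' the report exactly.
#'
#' @param config A named list (or YAML path) with blocks `data` (either
#'   `scenario = <scenario_config args>` or `cohort_dir = <path>`),
#'   `windowing`, `fusion` (`mode`, `prob_mode`), `evaluation` (`protocol`
#'   "cv", "fixed_split" or "gridsearch" plus its parameters) and `seed`.
#' @param out_dir Optional output directory for artifacts.
#' @return The protocol's `eval_report` (for `"gridsearch"`, its full result
#'   list).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_pipeline_config(config)
  seed <- config$seed

  if (!is.null(config$data$cohort_dir)) {
    cohort <- read_cohort(config$data$cohort_dir)
    catalog <- attr(cohort, "catalog")
  } else {
    sc <- do.call(scenario_config, c(config$data$scenario,
                                     if (is.null(config$data$scenario$seed))
                                       list(seed = seed)))
    if (isTRUE(config$data$confusable)) sc <- make_confusable_design(sc)
    cohort <- generate_cohort(sc)
    catalog <- sc$catalog
  }

  mode <- config$fusion$mode
  modality <- if (mode == "imu") "imu" else "fused"
  wargs <- config$windowing
  instances <- do.call(cohort_instances,
                       c(list(cohort = cohort, catalog = catalog,
                              modality = modality), wargs))

  ev <- config$evaluation
  result <- switch(ev$protocol,
    cv = repeated_cv(instances, mode = mode,
                     k = ev$k %||% 5L, repeats = ev$repeats %||% 100L,
                     seed = seed, prob_mode = config$fusion$prob_mode),
    fixed_split = fixed_split_eval(instances, ev$train_subjects,
                                   ev$test_subjects, mode = mode,
                                   resample_balanced =
                                     isTRUE(ev$resample_balanced),
                                   seed = seed,
                                   prob_mode = config$fusion$prob_mode),
    gridsearch = grid_search(instances, mode = mode,
                             grid = as.data.frame(ev$grid),
                             train_fraction = ev$train_fraction %||% 0.8,
                             inner_k = ev$inner_k %||% 5L, seed = seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    report <- if (ev$protocol == "gridsearch") result$report else result
    write_report(report, file.path(out_dir, "report"))
    yaml::write_yaml(list(config = config, seed = seed,
                          n_instances = n_instances(instances),
                          classes = sort(unique(instances$meta$label))),
                     file.path(out_dir, "run_log.yaml"))
  }
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_pipeline_config <- function(config) {
  known <- c("data", "windowing", "fusion", "evaluation", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$seed)) stop("config requires a seed")
  if (is.null(config$data)) stop("config requires a data block")
  if (is.null(config$data$cohort_dir) && is.null(config$data$scenario)) {
    stop("data block needs either cohort_dir or scenario")
  }
  config$fusion <- config$fusion %||% list()
  config$fusion$mode <- config$fusion$mode %||% "late"
  if (!config$fusion$mode %in% c("late", "early", "imu", "vision")) {
    stop("fusion mode must be late, early, imu or vision")
  }
  config$fusion$prob_mode <- config$fusion$prob_mode %||% "in_sample"
  config$windowing <- config$windowing %||% list()
  config$evaluation <- config$evaluation %||% list(protocol = "cv")
  if (!config$evaluation$protocol %in% c("cv", "fixed_split", "gridsearch")) {
    stop("evaluation protocol must be cv, fixed_split or gridsearch")
  }
  config
}
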