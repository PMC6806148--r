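#' Construct a fused instance set
#'
#' The instance table of the learning stage: per aligned window, the
#' 84-dimensional left+right inertial block, the hand-object interaction
#' block, the activity label, and provenance (subject, session, window index
#' and timespan) needed for leakage-aware subsampling and subject splits.
#' Either feature block may be absent for single-modality sets.
#'
#' @param meta Data frame with columns `subject`, `session`, `index`,
#'   `start_ms`, `end_ms`, `label`.
#' @param imu Numeric matrix (rows match `meta`) or `NULL`.
#' @param vision Numeric matrix (rows match `meta`) or `NULL`.
#' @return A `fused_instances` object.
#' @export
fused_instances <- function(meta, imu = NULL, vision = NULL) {
  need <- c("subject", "session", "index", "start_ms", "end_ms", "label")
  if (!all(need %in% names(meta))) {
    stop("meta needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(imu) && is.null(vision)) {
    stop("at least one feature block must be present")
  }
  for (block in list(imu, vision)) {
    if (!is.null(block) && nrow(block) != nrow(meta)) {
      stop("feature block rows must match meta rows")
    }
  }
  rownames(meta) <- NULL
  structure(list(meta = meta, imu = imu, vision = vision),
            class = "fused_instances")
}

#' @export
print.fused_instances <- function(x, ...) {
  cat(sprintf("<fused_instances> %d instances, %d classes (imu: %s, vision: %s)\n",
              nrow(x$meta), length(unique(x$meta$label)),
              if (is.null(x$imu)) "-" else ncol(x$imu),
              if (is.null(x$vision)) "-" else ncol(x$vision)))
  invisible(x)
}

#' Number of instances
#' @param x A `fused_instances` object.
#' @return Integer count.
#' @export
n_instances <- function(x) nrow(x$meta)

#' Subset instances by row
#' @param x A `fused_instances` object.
#' @param i Row index (integer or logical).
#' @return The subset, a `fused_instances` object.
#' @export
subset_instances <- function(x, i) {
  fused_instances(x$meta[i, , drop = FALSE],
                  if (is.null(x$imu)) NULL else x$imu[i, , drop = FALSE],
                  if (is.null(x$vision)) NULL else x$vision[i, , drop = FALSE])
}

#' Concatenate instance sets
#' @param sets List of `fused_instances` with identical block layouts.
#' @return One `fused_instances` object.
#' @export
bind_instances <- function(sets) {
  stopifnot(length(sets) > 0L)
  meta <- do.call(rbind, lapply(sets, `[[`, "meta"))
  imu <- if (is.null(sets[[1L]]$imu)) NULL else
    do.call(rbind, lapply(sets, `[[`, "imu"))
  vision <- if (is.null(sets[[1L]]$vision)) NULL else
    do.call(rbind, lapply(sets, `[[`, "vision"))
  fused_instances(meta, imu, vision)
}

#' De-overlap an instance set
#'
#' See [deoverlap_keep()]; operates on the stored grid indices.
#'
#' @param x A `fused_instances` object.
#' @param modality_mode `"vision_or_fused"` or `"imu_only"`.
#' @return The subsampled `fused_instances`.
#' @export
deoverlap_subsample <- function(x, modality_mode = c("vision_or_fused",
                                                     "imu_only")) {
  subset_instances(x, deoverlap_keep(x$meta$index, match.arg(modality_mode)))
}

#' Early fusion: concatenated feature matrix
#'
#' Concatenates the inertial block (left then right wrist) with the vision
#' block into one row per instance, for training a single model on all
#' modalities.
#'
#' @param x A `fused_instances` object with both blocks.
#' @return Numeric matrix `[imu_left | imu_right | vision]`.
#' @export
early_fuse <- function(x) {
  if (is.null(x$imu) || is.null(x$vision)) {
    stop("early fusion requires both feature blocks")
  }
  cbind(x$imu, x$vision)
}

#' Train a late-fusion (probability stacking) model
#'
#' One base model is fit per modality — by default a random forest on the
#' concatenated inertial features and a logistic model on the vision features.
#' Each base model's per-class probabilities are appended to its own feature
#' block, the two augmented blocks are concatenated, and a meta model is fit
#' on the result. `prob_mode` controls the provenance of the training-time
#' probabilities: `"in_sample"` uses the base models' predictions on their
#' own training data (the literal stacked-pipeline description);
#' `"out_of_fold"` obtains them from an internal stratified 5-fold
#' cross-fit, which curbs stacking leakage.
#'
#' @param train A `fused_instances` set with both blocks and labels.
#' @param base_imu,base_vis,meta [classifier_spec()]s for the inertial base,
#'   vision base and fusion meta model.
#' @param prob_mode `"in_sample"` (default) or `"out_of_fold"`.
#' @param seed Integer seed.
#' @return A `late_fusion_model` exposing [predict()] with class labels and
#'   probabilities.
#' @export
late_fuse_train <- function(train,
                            base_imu = classifier_spec("random_forest"),
                            base_vis = classifier_spec("logistic"),
                            meta = classifier_spec("logistic"),
                            prob_mode = c("in_sample", "out_of_fold"),
                            seed = 1L) {
  prob_mode <- match.arg(prob_mode)
  if (is.null(train$imu) || is.null(train$vision)) {
    stop("late fusion requires both feature blocks")
  }
  if (n_instances(train) == 0L) stop("empty training set")
  y <- factor(train$meta$label)
  fit_imu <- fit_classifier(base_imu, train$imu, y, seed = seed)
  fit_vis <- fit_classifier(base_vis, train$vision, y, seed = seed + 1L)
  p_imu <- stack_probs(base_imu, train$imu, y, fit_imu, prob_mode, seed)
  p_vis <- stack_probs(base_vis, train$vision, y, fit_vis, prob_mode,
                       seed + 1L)
  meta_x <- cbind(train$imu, prob_cols(p_imu, "imu"),
                  train$vision, prob_cols(p_vis, "vis"))
  fit_meta <- fit_classifier(meta, meta_x, y, seed = seed + 2L)
  structure(list(base_imu = fit_imu, base_vis = fit_vis, meta = fit_meta,
                 classes = levels(y), prob_mode = prob_mode, seed = seed),
            class = "late_fusion_model")
}

prob_cols <- function(p, tag) {
  colnames(p) <- paste0("p_", tag, "_", colnames(p))
  p
}

stack_probs <- function(spec, x, y, full_fit, prob_mode, seed) {
  if (prob_mode == "in_sample") return(predict_prob(full_fit, x))
  folds <- make_folds(y, k = 5L, seed = seed + 1000L, stratified = TRUE)
  p <- matrix(NA_real_, length(y), nlevels(y),
              dimnames = list(NULL, levels(y)))
  for (f in seq_len(max(folds))) {
    hold <- folds == f
    fit <- fit_classifier(spec, x[!hold, , drop = FALSE], y[!hold],
                          seed = seed + f)
    p[hold, ] <- predict_prob(fit, x[hold, , drop = FALSE])[, levels(y)]
  }
  p
}

#' @export
print.late_fusion_model <- function(x, ...) {
  cat(sprintf("<late_fusion_model> %s + %s -> %s (%s probabilities), %d classes\n",
              x$base_imu$spec$family, x$base_vis$spec$family,
              x$meta$spec$family, x$prob_mode, length(x$classes)))
  invisible(x)
}

#' Predict with a late-fusion model
#'
#' @param object A `late_fusion_model`.
#' @param newdata A `fused_instances` set with both blocks.
#' @param ... Unused.
#' @return List with `class` (character vector) and `prob` (matrix, rows
#'   summing to 1).
#' @export
predict.late_fusion_model <- function(object, newdata, ...) {
  if (is.null(newdata$imu) || is.null(newdata$vision)) {
    stop("late-fusion prediction requires both feature blocks")
  }
  if (n_instances(newdata) == 0L) {
    return(list(class = character(0),
                prob = matrix(numeric(0), 0L, length(object$classes),
                              dimnames = list(NULL, object$classes))))
  }
  p_imu <- predict_prob(object$base_imu, newdata$imu)
  p_vis <- predict_prob(object$base_vis, newdata$vision)
  meta_x <- cbind(newdata$imu, prob_cols(p_imu, "imu"),
                  newdata$vision, prob_cols(p_vis, "vis"))
  prob <- predict_prob(object$meta, meta_x)
  list(class = object$classes[max.col(prob, ties.method = "first")],
       prob = prob)
}

#' Fit an activity model in one of four modality modes
#'
#' Convenience wrapper used by all evaluation protocols: `"imu"` and
#' `"vision"` fit a single classifier on one block, `"early"` fits one
#' classifier on the concatenated blocks, `"late"` builds the probability
#' stack of [late_fuse_train()].
#'
#' @param train A `fused_instances` training set.
#' @param mode `"imu"`, `"vision"`, `"early"` or `"late"`.
#' @param imu_spec,vis_spec,meta_spec Classifier specs (defaults: random
#'   forest for inertial, logistic for vision, logistic meta).
#' @param prob_mode Probability provenance for late fusion.
#' @param seed Integer seed.
#' @return An `activity_model`.
#' @export
fit_activity_model <- function(train, mode = c("late", "early", "imu", "vision"),
                               imu_spec = classifier_spec("random_forest"),
                               vis_spec = classifier_spec("logistic"),
                               meta_spec = classifier_spec("logistic"),
                               prob_mode = "in_sample", seed = 1L) {
  mode <- match.arg(mode)
  y <- factor(train$meta$label)
  fit <- switch(mode,
    imu = fit_classifier(imu_spec, train$imu, y, seed = seed),
    vision = fit_classifier(vis_spec, train$vision, y, seed = seed),
    early = fit_classifier(meta_spec, early_fuse(train), y, seed = seed),
    late = late_fuse_train(train, imu_spec, vis_spec, meta_spec,
                           prob_mode = prob_mode, seed = seed))
  structure(list(mode = mode, fit = fit, classes = levels(y)),
            class = "activity_model")
}

#' Predict with an activity model
#' @param object An `activity_model`.
#' @param newdata A `fused_instances` set carrying the blocks the model was
#'   trained on.
#' @param ... Unused.
#' @return List with `class` and `prob` (see [predict.late_fusion_model()]).
#' @export
predict.activity_model <- function(object, newdata, ...) {
  if (n_instances(newdata) == 0L) {
    return(list(class = character(0),
                prob = matrix(numeric(0), 0L, length(object$classes),
                              dimnames = list(NULL, object$classes))))
  }
  switch(object$mode,
    imu = {
      prob <- predict_prob(object$fit, newdata$imu)
      list(class = object$classes[max.col(prob, ties.method = "first")],
           prob = prob)
    },
    vision = {
      prob <- predict_prob(object$fit, newdata$vision)
      list(class = object$classes[max.col(prob, ties.method = "first")],
           prob = prob)
    },
    early = {
      prob <- predict_prob(object$fit, early_fuse(newdata))
      list(class = object$classes[max.col(prob, ties.method = "first")],
           prob = prob)
    },
    late = predict(object$fit, newdata))
}
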