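#' Per-class precision, recall and F1
#'
#' One-vs-rest precision and recall per class, F1 as their harmonic mean
#' (0 when both are 0), and unweighted macro averages over `class_set`
#' (including the `"none"` background class unless it is excluded from
#' `class_set`). A class with no predicted positives scores precision 0 by
#' convention.
#'
#' @param predictions,truths Character vectors of equal length.
#' @param class_set Classes to report; defaults to the classes present in
#'   `truths` or `predictions`, sorted.
#' @return An `eval_report`: list with `per_class` (data frame `class`,
#'   `precision`, `recall`, `f1`) and `macro` (named vector).
#' @export
score <- function(predictions, truths, class_set = NULL) {
  if (length(predictions) != length(truths)) {
    stop("predictions and truths must have equal length")
  }
  if (is.null(class_set)) {
    class_set <- sort(unique(c(truths, predictions)))
  }
  unknown <- setdiff(unique(c(truths, predictions)), class_set)
  if (length(unknown) > 0L) {
    stop("labels outside class_set: ", paste(unknown, collapse = ", "))
  }
  prf <- t(vapply(class_set, function(cl) {
    tp <- sum(predictions == cl & truths == cl)
    fp <- sum(predictions == cl & truths != cl)
    fn <- sum(predictions != cl & truths == cl)
    prec <- if (tp + fp == 0L) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0L) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(precision = prec, recall = rec, f1 = f1)
  }, numeric(3)))
  per_class <- data.frame(class = class_set, prf, row.names = NULL)
  structure(list(per_class = per_class,
                 macro = c(precision = mean(per_class$precision),
                           recall = mean(per_class$recall),
                           f1 = mean(per_class$f1)),
                 n = length(truths)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>")
  if (!is.null(x$scheme)) cat(" ", x$scheme, sep = "")
  cat(sprintf(" (n = %d)\n", x$n))
  df <- x$per_class
  df[-1L] <- lapply(df[-1L], round, 3L)
  print(df, row.names = FALSE)
  cat(sprintf("macro: precision %.3f, recall %.3f, F1 %.3f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  invisible(x)
}

# Stratified (or plain) k-fold assignment; returns integer fold ids.
make_folds <- function(y, k, seed, stratified = TRUE) {
  y <- factor(y)
  n <- length(y)
  set.seed(seed)
  folds <- integer(n)
  if (stratified) {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    folds <- sample(rep_len(seq_len(k), n))
  }
  folds
}

average_reports <- function(reports) {
  per <- lapply(reports, `[[`, "per_class")
  out <- per[[1L]]
  for (col in c("precision", "recall", "f1")) {
    out[[col]] <- rowMeans(vapply(per, `[[`, numeric(nrow(out)), col))
  }
  structure(list(per_class = out,
                 macro = c(precision = mean(out$precision),
                           recall = mean(out$recall),
                           f1 = mean(out$f1)),
                 n = reports[[1L]]$n),
            class = "eval_report")
}

#' Repeated k-fold cross-validation
#'
#' For each repeat a fresh fold partition is drawn (stratified by class by
#' default so rare classes reach every fold), every fold is predicted by a
#' model trained on the remaining folds, per-class metrics are computed on
#' the pooled predictions of the repeat, and metrics are averaged across
#' repeats. Overlapping windows should be removed with
#' [deoverlap_subsample()] beforehand so folds never share raw samples.
#'
#' @param instances A `fused_instances` set.
#' @param mode Modality mode, see [fit_activity_model()].
#' @param k Folds (default 5; lowered with a warning when a class has fewer
#'   than `k` instances).
#' @param repeats Number of independent fold redraws (default 100).
#' @param seed Integer seed; repeat `r` uses `seed + r`.
#' @param stratified Stratify folds by class (default `TRUE`).
#' @param ... Passed to [fit_activity_model()] (classifier specs,
#'   `prob_mode`).
#' @return An `eval_report` with attributes of the fold scheme.
#' @export
repeated_cv <- function(instances, mode = "late", k = 5L, repeats = 100L,
                        seed = 1L, stratified = TRUE, ...) {
  y <- factor(instances$meta$label)
  if (nlevels(y) < 2L) stop("cross-validation needs at least two classes")
  min_count <- min(table(y))
  if (min_count < k) {
    warning("smallest class has ", min_count, " instances; lowering k")
    k <- max(2L, min_count)
  }
  class_set <- levels(y)
  reports <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    folds <- make_folds(y, k, seed = seed + r, stratified = stratified)
    pred <- character(length(y))
    for (f in seq_len(k)) {
      hold <- folds == f
      model <- fit_activity_model(subset_instances(instances, !hold),
                                  mode = mode, seed = seed + r, ...)
      pred[hold] <- predict(model, subset_instances(instances, hold))$class
    }
    reports[[r]] <- score(pred, as.character(y), class_set)
  }
  out <- average_reports(reports)
  out$scheme <- sprintf("%d-fold CV x %d repeats (%s)", k, repeats, mode)
  out$k <- k
  out$repeats <- repeats
  out$seed <- seed
  out
}

#' Fixed cross-subject split evaluation
#'
#' Trains on the instances of `train_subjects` and evaluates on the disjoint
#' `test_subjects`. With `resample_balanced = TRUE` the training set (only)
#' is randomly oversampled so every class reaches the majority-class count,
#' simulating an even class distribution.
#'
#' @param instances A `fused_instances` set.
#' @param train_subjects,test_subjects Disjoint character vectors of subject
#'   ids.
#' @param mode Modality mode.
#' @param resample_balanced Oversample minority classes in training (default
#'   `FALSE`).
#' @param seed Integer seed.
#' @param ... Passed to [fit_activity_model()].
#' @return An `eval_report` on the test subjects.
#' @export
fixed_split_eval <- function(instances, train_subjects, test_subjects,
                             mode = "late", resample_balanced = FALSE,
                             seed = 1L, ...) {
  if (length(intersect(train_subjects, test_subjects)) > 0L) {
    stop("train and test subject sets overlap")
  }
  subj <- instances$meta$subject
  train <- subset_instances(instances, subj %in% train_subjects)
  test <- subset_instances(instances, subj %in% test_subjects)
  if (n_instances(train) == 0L || n_instances(test) == 0L) {
    stop("empty train or test split")
  }
  if (resample_balanced) {
    train <- oversample_balanced(train, seed = seed)
  }
  model <- fit_activity_model(train, mode = mode, seed = seed, ...)
  pred <- predict(model, test)$class
  out <- score(pred, test$meta$label,
               sort(unique(instances$meta$label)))
  out$scheme <- sprintf("fixed split %s -> %s (%s)",
                        paste(train_subjects, collapse = "+"),
                        paste(test_subjects, collapse = "+"), mode)
  out
}

#' Oversample a training set to an even class distribution
#'
#' Each minority class is resampled with replacement up to the majority-class
#' count. Only ever applied to training data.
#'
#' @param train A `fused_instances` set.
#' @param seed Integer seed.
#' @return The balanced `fused_instances`.
#' @export
oversample_balanced <- function(train, seed = 1L) {
  y <- train$meta$label
  counts <- table(y)
  target <- max(counts)
  set.seed(seed)
  idx <- unlist(lapply(names(counts), function(cl) {
    have <- which(y == cl)
    if (length(have) >= target) have else
      c(have, sample(have, target - length(have), replace = TRUE))
  }))
  subset_instances(train, sort(idx))
}

#' Hyperparameter grid search with an inner cross-validation
#'
#' Splits the instances into a stratified train/test partition (default
#' 80/20), evaluates every grid point by stratified `inner_k`-fold
#' cross-validation on the training split (mean macro F1), selects the best
#' point (ties: first in grid order), refits it on the full training split
#' and reports test metrics.
#'
#' @param instances A `fused_instances` set.
#' @param mode Modality mode; the grid applies to the single classifier of
#'   that mode (`"imu"`, `"vision"` or `"early"`).
#' @param grid Data frame of classifier parameters, one row per candidate;
#'   columns must be [classifier_spec()] arguments plus `family`.
#' @param train_fraction Training share (default 0.8).
#' @param inner_k Inner folds (default 5).
#' @param seed Integer seed.
#' @return List with `best_params` (one-row data frame), `inner_f1` (mean
#'   inner macro F1 per grid row) and `report` (test-set `eval_report`).
#' @export
grid_search <- function(instances, mode = c("imu", "vision", "early"),
                        grid, train_fraction = 0.8, inner_k = 5L,
                        seed = 1L) {
  mode <- match.arg(mode)
  if (nrow(grid) == 0L) stop("empty parameter grid")
  y <- factor(instances$meta$label)
  folds <- make_folds(y, k = round(1 / (1 - train_fraction)), seed = seed,
                      stratified = TRUE)
  test_idx <- folds == 1L  # one stratified fold = the held-out test share
  train <- subset_instances(instances, !test_idx)
  test <- subset_instances(instances, test_idx)
  inner_f1 <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    spec <- spec_from_row(grid[g, , drop = FALSE])
    inner_f1[g] <- inner_cv_f1(train, mode, spec, inner_k, seed)
  }
  best <- which.max(inner_f1)  # ties: first in grid order
  best_spec <- spec_from_row(grid[best, , drop = FALSE])
  model <- fit_mode_single(train, mode, best_spec, seed)
  pred <- predict(model, test)$class
  report <- score(pred, test$meta$label, levels(y))
  report$scheme <- sprintf("grid search %d points, %s", nrow(grid), mode)
  list(best_params = grid[best, , drop = FALSE], inner_f1 = inner_f1,
       report = report)
}

# One grid row -> classifier_spec; NA cells (parameters of the other
# family) are dropped so defaults apply.
spec_from_row <- function(row) {
  params <- as.list(row)
  params <- params[!vapply(params, function(v) is.na(v[1L]), logical(1))]
  do.call(classifier_spec, params)
}

fit_mode_single <- function(train, mode, spec, seed) {
  switch(mode,
    imu = fit_activity_model(train, "imu", imu_spec = spec, seed = seed),
    vision = fit_activity_model(train, "vision", vis_spec = spec, seed = seed),
    early = fit_activity_model(train, "early", meta_spec = spec, seed = seed))
}

inner_cv_f1 <- function(train, mode, spec, inner_k, seed) {
  y <- factor(train$meta$label)
  k <- min(inner_k, min(table(y)))
  folds <- make_folds(y, k = k, seed = seed + 17L, stratified = TRUE)
  pred <- character(length(y))
  for (f in seq_len(k)) {
    hold <- folds == f
    model <- fit_mode_single(subset_instances(train, !hold), mode, spec,
                             seed + f)
    pred[hold] <- predict(model, subset_instances(train, hold))$class
  }
  unname(score(pred, as.character(y), levels(y))$macro["f1"])
}
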