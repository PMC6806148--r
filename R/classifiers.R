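#' Specify a base classifier
#'
#' Two algorithm families are supported, mirroring the configurations that
#' work well for windowed activity features: a random-forest ensemble
#' (`randomForest`) and a regularized multinomial logistic model. The
#' logistic family exposes two optimizers: `"newton"` (quasi-Newton BFGS via
#' `nnet::multinom`, with L2 penalty `decay = 1/C`) and `"simple"`
#' (coordinate-wise first-order fitting via `glmnet` with `alpha = 0`,
#' `lambda = 1/(C * n)`). `C` is the inverse regularization strength: larger
#' C, weaker penalty.
#'
#' @param family `"random_forest"` or `"logistic"`.
#' @param n_trees Forest size (default 100).
#' @param max_depth Maximum tree depth; `NULL` (default) grows full trees.
#'   Internally mapped to a `maxnodes = 2^max_depth` cap.
#' @param min_node Minimum samples per leaf (default 1).
#' @param mtry Features tried per split: `"sqrt"` (default) or `"all"`.
#' @param C Inverse regularization strength of the logistic model (default 1).
#' @param max_iter Iteration cap of the logistic optimizer (default 200).
#' @param optimizer `"newton"` or `"simple"` (logistic family only).
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(family = c("random_forest", "logistic"),
                            n_trees = 100L, max_depth = NULL, min_node = 1L,
                            mtry = c("sqrt", "all"),
                            C = 1, max_iter = 200L,
                            optimizer = c("newton", "simple")) {
  family <- match.arg(family)
  spec <- if (family == "random_forest") {
    list(family = family, n_trees = as.integer(n_trees),
         max_depth = if (is.null(max_depth)) NULL else as.integer(max_depth),
         min_node = as.integer(min_node), mtry = match.arg(mtry))
  } else {
    if (C <= 0) stop("C must be positive")
    list(family = family, C = C, max_iter = as.integer(max_iter),
         optimizer = match.arg(optimizer))
  }
  structure(spec, class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("<classifier_spec>", x$family, "\n")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Fit a base classifier
#'
#' @param spec A [classifier_spec()].
#' @param x Numeric feature matrix (named columns).
#' @param y Labels (character or factor). Every level of `y` must be present.
#' @param seed Integer seed controlling any stochastic fitting.
#' @return A `fitted_classifier` with elements `spec`, `classes`, `fit`.
#' @export
fit_classifier <- function(spec, x, y, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- if (is.factor(y)) y else factor(y)
  present <- levels(y) %in% unique(as.character(y))
  if (!all(present)) {
    stop("classes absent from training data: ",
         paste(levels(y)[!present], collapse = ", "))
  }
  if (nlevels(y) < 2L) stop("training data contains a single class")
  center <- scale_ <- NULL
  if (spec$family == "logistic") {
    # standardize so the L2 penalty treats features comparably
    center <- colMeans(x)
    scale_ <- apply(x, 2L, stats::sd)
    scale_[scale_ == 0] <- 1
    x <- sweep(sweep(x, 2L, center), 2L, scale_, "/")
  }
  fit <- switch(
    spec$family,
    random_forest = {
      maxnodes <- if (is.null(spec$max_depth)) NULL else
        min(2L^spec$max_depth, nrow(x))
      mtry <- if (spec$mtry == "all") ncol(x) else
        max(1L, floor(sqrt(ncol(x))))
      set.seed(seed)
      randomForest::randomForest(x = x, y = y, ntree = spec$n_trees,
                                 nodesize = spec$min_node,
                                 maxnodes = maxnodes, mtry = mtry)
    },
    logistic = {
      if (spec$optimizer == "newton") {
        df <- data.frame(.y = y, x, check.names = FALSE)
        n_w <- (ncol(x) + 1L) * (nlevels(y) - 1L) + nlevels(y)
        nnet::multinom(.y ~ ., data = df, decay = 1 / spec$C,
                       maxit = spec$max_iter, trace = FALSE,
                       MaxNWts = max(10000L, n_w + 1L))
      } else {
        glmnet::glmnet(x, y, family = "multinomial", alpha = 0,
                       lambda = 1 / (spec$C * nrow(x)),
                       maxit = max(spec$max_iter * 1000L, 100000L))
      }
    })
  structure(list(spec = spec, classes = levels(y), fit = fit,
                 feature_names = colnames(x), center = center,
                 scale = scale_),
            class = "fitted_classifier")
}

#' Class-probability predictions of a fitted classifier
#'
#' @param model A `fitted_classifier`.
#' @param x Feature matrix with the training columns.
#' @return Matrix `nrow(x)` x `length(model$classes)`; rows sum to 1, columns
#'   ordered and named by `model$classes`.
#' @export
predict_prob <- function(model, x) {
  stopifnot(inherits(model, "fitted_classifier"))
  x <- as.matrix(x)
  if (ncol(x) != length(model$feature_names)) {
    stop("feature dimension mismatch: expected ",
         length(model$feature_names), " columns (",
         paste(utils::head(model$feature_names, 4L), collapse = ", "),
         ", ...), got ", ncol(x))
  }
  colnames(x) <- model$feature_names
  if (!is.null(model$center)) {
    x <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  }
  cls <- model$classes
  if (nrow(x) == 0L) {
    return(matrix(numeric(0), 0L, length(cls), dimnames = list(NULL, cls)))
  }
  p <- switch(
    model$spec$family,
    random_forest = predict(model$fit, newdata = x, type = "prob"),
    logistic = {
      if (model$spec$optimizer == "newton") {
        pr <- predict(model$fit, newdata = data.frame(x, check.names = FALSE),
                      type = "probs")
        if (length(cls) == 2L) {
          # vector (or 1-col) of P(second level)
          pr <- matrix(c(1 - as.numeric(pr), as.numeric(pr)), ncol = 2L,
                       dimnames = list(NULL, cls))
        } else if (is.null(dim(pr))) {  # single row, >2 classes
          pr <- matrix(pr, 1L, dimnames = list(NULL, names(pr)))
        }
        pr
      } else {
        pr <- predict(model$fit, newx = x, type = "response")
        pr[, , 1L, drop = TRUE]
      }
    })
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L, dimnames = list(NULL, names(p)))
  p <- p[, cls, drop = FALSE]
  p / rowSums(p)
}

#' Class-label predictions of a fitted classifier
#' @inheritParams predict_prob
#' @return Character vector of predicted classes (argmax probability; ties go
#'   to the earlier class in `model$classes`).
#' @export
predict_class <- function(model, x) {
  p <- predict_prob(model, x)
  model$classes[max.col(p, ties.method = "first")]
}
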