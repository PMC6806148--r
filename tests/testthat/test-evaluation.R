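# small helper reusing the generator from the fusion tests would couple the
# files; build a minimal separable set locally instead
sep_instances <- function(n_per_class = 15, n_classes = 3, sd = 0.1,
                          seed = 1, subjects = c("s1", "s2")) {
  set.seed(seed)
  n <- n_per_class * n_classes
  cls <- rep(seq_len(n_classes), each = n_per_class)
  imu <- matrix(rnorm(n * 10, sd = sd), n) + 3 * cls
  vision <- matrix(rnorm(n * 4, sd = sd), n) + 2 * cls
  colnames(imu) <- paste0("i", 1:10); colnames(vision) <- paste0("v", 1:4)
  meta <- data.frame(subject = rep(subjects, length.out = n), session = "1",
                     index = seq_len(n) - 1L,
                     start_ms = (seq_len(n) - 1) * 400,
                     end_ms = seq_len(n) * 400,
                     label = paste0("act", cls))
  fused_instances(meta, imu = imu, vision = vision)
}

test_that("score reproduces hand-computed confusion-matrix metrics", {
  r <- score(c("A", "B", "B", "B"), c("A", "A", "B", "B"))
  a <- r$per_class[r$per_class$class == "A", ]
  b <- r$per_class[r$per_class$class == "B", ]
  expect_equal(a$precision, 1.0)
  expect_equal(a$recall, 0.5)
  expect_equal(a$f1, 2 / 3)
  expect_equal(b$precision, 2 / 3)
  expect_equal(b$recall, 1.0)
  expect_equal(b$f1, 0.8)
  expect_equal(unname(r$macro["f1"]), mean(c(2 / 3, 0.8)))

  perfect <- score(c("x", "y"), c("x", "y"))
  expect_true(all(perfect$per_class[-1] == 1))

  # a class never predicted: precision, recall, F1 all 0
  z <- score(c("a", "a", "a"), c("a", "a", "b"))
  zb <- z$per_class[z$per_class$class == "b", ]
  expect_equal(unlist(zb[-1], use.names = FALSE), c(0, 0, 0))

  expect_error(score("a", "b", class_set = "a"), "outside class_set")
  expect_error(score(c("a", "b"), "a"), "equal length")
})

test_that("F1 is the harmonic mean of its precision and recall", {
  set.seed(2)
  for (i in 1:20) {
    truth <- sample(letters[1:4], 60, replace = TRUE)
    pred <- sample(letters[1:4], 60, replace = TRUE)
    r <- score(pred, truth, letters[1:4])$per_class
    h <- ifelse(r$precision + r$recall == 0, 0,
                2 * r$precision * r$recall / (r$precision + r$recall))
    expect_equal(r$f1, h)
    expect_true(all(r$precision >= 0 & r$precision <= 1))
  }
})

test_that("repeated CV: determinism, separability, majority analytics", {
  inst <- sep_instances()
  r1 <- repeated_cv(inst, mode = "early", k = 5, repeats = 2, seed = 3)
  r2 <- repeated_cv(inst, mode = "early", k = 5, repeats = 2, seed = 3)
  expect_identical(r1$per_class, r2$per_class)
  expect_equal(unname(r1$macro["f1"]), 1.0)  # separable

  expect_error(repeated_cv(subset_instances(inst, inst$meta$label == "act1"),
                           repeats = 1), "two classes")

  # a classifier always predicting the majority class on balanced 2 classes
  # has macro recall 0.5: verified through the metric path
  truth <- rep(c("a", "b"), each = 10)
  expect_equal(unname(score(rep("a", 20), truth)$macro["recall"]), 0.5)
})

test_that("k is lowered with a warning when a class is too small", {
  inst <- sep_instances(n_per_class = 3)
  expect_warning(r <- repeated_cv(inst, mode = "early", k = 5, repeats = 1,
                                  seed = 1), "lowering k")
  expect_equal(r$k, 3L)
})

test_that("fixed split: leakage-free, balanced resampling, subject checks", {
  inst <- sep_instances(n_per_class = 20, seed = 5)
  # unbalance one class for subject s1
  drop <- which(inst$meta$label == "act1" & inst$meta$subject == "s1")[1:5]
  inst <- subset_instances(inst, setdiff(seq_len(n_instances(inst)), drop))

  expect_error(fixed_split_eval(inst, "s1", "s1"), "overlap")

  r <- fixed_split_eval(inst, "s1", "s2", mode = "early", seed = 2)
  expect_true(all(r$per_class$f1 >= 0 & r$per_class$f1 <= 1))
  expect_equal(unname(r$macro["f1"]), 1.0)  # subject-invariant signatures

  # resampling equalizes training counts and never touches the test set
  train <- subset_instances(inst, inst$meta$subject == "s1")
  bal <- oversample_balanced(train, seed = 7)
  expect_true(all(table(bal$meta$label) == max(table(train$meta$label))))
  test_before <- subset_instances(inst, inst$meta$subject == "s2")
  r2 <- fixed_split_eval(inst, "s1", "s2", mode = "early",
                         resample_balanced = TRUE, seed = 2)
  test_after <- subset_instances(inst, inst$meta$subject == "s2")
  expect_identical(test_before, test_after)
  expect_equal(unname(r2$macro["f1"]), 1.0)
})

test_that("grid search selects sensible parameters deterministically", {
  inst <- sep_instances(n_per_class = 12, sd = 0.5, seed = 8)
  one <- data.frame(family = "logistic", C = 1)
  g1 <- grid_search(inst, "early", one, seed = 4)
  expect_equal(g1$best_params$C, 1)

  # degenerate forest (1 stump) loses to a real one on separable data
  rf_grid <- data.frame(family = "random_forest",
                        n_trees = c(1L, 60L), max_depth = c(1L, 8L))
  g2 <- grid_search(inst, "imu", rf_grid, seed = 4)
  expect_equal(g2$best_params$n_trees, 60L)
  expect_gte(g2$inner_f1[2], g2$inner_f1[1])

  g3 <- grid_search(inst, "imu", rf_grid, seed = 4)
  expect_identical(g2$best_params, g3$best_params)
  expect_error(grid_search(inst, "imu", rf_grid[0, ]), "empty")
})

test_that("no window timespan crosses a fold for the same subject-session", {
  inst <- deoverlap_subsample(sep_instances(n_per_class = 16), "vision_or_fused")
  y <- inst$meta$label
  folds <- actifuse:::make_folds(y, 5, seed = 9)
  key <- paste(inst$meta$subject, inst$meta$session)
  for (f in 1:5) {
    tr <- inst$meta[folds != f, ]; te <- inst$meta[folds == f, ]
    for (k in unique(key)) {
      a <- tr[paste(tr$subject, tr$session) == k, ]
      b <- te[paste(te$subject, te$session) == k, ]
      if (nrow(a) == 0 || nrow(b) == 0) next
      inter <- outer(a$start_ms, b$end_ms, "-") < 0 &
        outer(a$end_ms, b$start_ms, "-") > 0
      expect_false(any(inter))
    }
  }
})
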