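test_that("generation is seed-deterministic", {
  cfg <- tiny_config(seed = 77)
  a <- generate_session(cfg, 1, 1)
  b <- generate_session(cfg, 1, 1)
  expect_identical(a, b)
  c2 <- generate_session(cfg, 1, 2)
  expect_false(identical(a$streams$left_wrist, c2$streams$left_wrist))
})

test_that("sampling grids are exact: 20 ms inertial, 40 ms frames", {
  sess <- generate_session(tiny_config(seed = 3), 1, 1)
  expect_equal(unique(diff(sess$streams$left_wrist$samples$t)), 20)
  expect_equal(unique(diff(sess$streams$right_wrist$samples$t)), 20)
  expect_equal(unique(diff(sess$detections$frames$frame_t)), 40)
})

test_that("stillness lead-in carries gravity plus noise only", {
  cfg <- tiny_config(seed = 9, stillness_lead_ms = 5000)
  sess <- generate_session(cfg, 1, 1)
  s <- sess$streams$left_wrist$samples
  lead <- s[s$t < 5000, ]
  sd0 <- cfg$accel_noise_sd
  expect_true(all(abs(lead$x) <= 4 * sd0))
  expect_true(all(abs(lead$y) <= 4 * sd0))
  expect_true(all(abs(lead$z - 9.81) <= 4 * sd0))
  # motion present after the lead
  act <- s[s$t >= 5000 & s$t < 6000, ]
  expect_gt(max(abs(act$z - 9.81)), 1)
})

test_that("degenerate overlap law puts the object at exactly 1", {
  cfg <- tiny_config(seed = 15, accel_noise_sd = 0,
                     detector = list(miss_prob = 0, fp_rate = 0,
                                     jitter_px = 0,
                                     confidence_range = c(0.9, 0.9)))
  cfg$object_models$take_snack$beta <- c(1, 0)
  sess <- generate_session(cfg, 1, 1)
  obj <- cfg$object_models$take_snack$objects
  ann <- sess$annotations
  snack <- ann[ann$class == "take_snack", ]
  fm <- actifuse:::frame_feature_matrix(sess$detections, cfg$catalog)
  in_snack <- sess$detections$frames$frame_t >= snack$start_ms &
    sess$detections$frames$frame_t < snack$end_ms
  expect_true(all(fm[in_snack, obj] == 1))
})

test_that("drawn overlaps match their Beta mean within 3 standard errors", {
  cfg <- scenario_config(subjects = 1, sessions_per_subject = 1,
                         activity_sequences = list(rep("take_snack", 6)),
                         duration_range_ms = c(4000, 4000),
                         detector = list(miss_prob = 0, fp_rate = 0,
                                         jitter_px = 0,
                                         confidence_range = c(0.9, 0.9)),
                         seed = 31)
  sess <- generate_session(cfg, 1, 1)
  obj <- cfg$object_models$take_snack$objects
  boxes <- sess$detections$boxes
  hands <- boxes[boxes$class == "person", ]
  objs <- boxes[boxes$class == obj, ]
  ov <- vapply(seq_len(nrow(objs)), function(i) {
    h <- hands[hands$frame_index == objs$frame_index[i], ]
    box_overlap(h[1, ], objs[i, ])
  }, numeric(1))
  b <- cfg$object_models$take_snack$beta
  mu <- b[1] / sum(b)
  sigma <- sqrt(b[1] * b[2] / (sum(b)^2 * (sum(b) + 1)))
  expect_lt(abs(mean(ov) - mu), 3 * sigma / sqrt(length(ov)))
})

test_that("the confusable design shares templates and objects as required", {
  cfg <- make_confusable_design(scenario_config(seed = 1))
  cls <- cfg$classes
  expect_length(cls, 4L)
  expect_identical(cfg$motion_templates[[cls[1]]],
                   cfg$motion_templates[[cls[2]]])
  expect_length(intersect(cfg$object_models[[cls[1]]]$objects,
                          cfg$object_models[[cls[2]]]$objects), 0L)
  expect_identical(cfg$object_models[[cls[3]]]$objects,
                   cfg$object_models[[cls[4]]]$objects)
  expect_false(identical(cfg$motion_templates[[cls[3]]],
                         cfg$motion_templates[[cls[4]]]))

  few <- scenario_config(activity_sequences = list(c("a", "b")), seed = 1)
  expect_error(make_confusable_design(few), "at least 4")
})

test_that("imu-only separation of the motion-sharing pair is at chance", {
  cfg <- confusable_moderate_noise_config(5)
  cfg$subjects <- 1L
  inst <- cohort_instances(generate_cohort(cfg))
  pair <- cfg$classes[1:2]
  sub <- subset_instances(inst, inst$meta$label %in% pair)
  accs <- vapply(1:5, function(s) {
    y <- factor(sub$meta$label)
    folds <- actifuse:::make_folds(y, 3, seed = s)
    pred <- character(length(y))
    for (f in 1:3) {
      m <- fit_activity_model(subset_instances(sub, folds != f), "imu",
                              seed = s)
      pred[folds == f] <- predict(m, subset_instances(sub, folds == f))$class
    }
    mean(pred == as.character(y))
  }, numeric(1))
  # binomial chance band around 0.5
  n <- n_instances(sub)
  expect_lt(abs(mean(accs) - 0.5), 3 * sqrt(0.25 / n) + 0.1)
})

test_that("scenario configs validate their inputs", {
  expect_error(scenario_config(), "seed is mandatory")
  expect_error(scenario_config(subjects = 0, seed = 1), ">= 1")
  expect_error(scenario_config(accel_noise_sd = -1, seed = 1), ">= 0")
  expect_error(scenario_config(duration_range_ms = c(5000, 3000), seed = 1),
               "duration")
  cfg <- tiny_config(seed = 2)
  cfg$motion_templates$take_snack <- NULL
  expect_error(do.call(scenario_config,
                       c(list(motion_templates = cfg$motion_templates,
                              activity_sequences = cfg$activity_sequences,
                              seed = 2))), "templates missing")
})

test_that("cohorts regenerate bit-identically and annotate truly", {
  cfg <- tiny_config(seed = 12)
  cfg$subjects <- 2L; cfg$sessions_per_subject <- 2L
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_equal(length(a), 4L)
  expect_identical(a[], b[])
  subj <- vapply(a, `[[`, character(1), "subject")
  expect_equal(sort(unique(subj)), c("subject1", "subject2"))
})
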