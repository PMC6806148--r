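test_that("hand-computed order statistics on {1,2,3,4}", {
  s <- data.frame(t = 0:3 * 20, x = c(1, 2, 3, 4), y = c(1, 2, 3, 4),
                  z = c(1, 2, 3, 4))
  f <- time_domain_features(s)
  expect_equal(f[["x_mean"]], 2.5)
  expect_equal(f[["x_median"]], 2.5)
  expect_equal(f[["x_variance"]], 1.25)
  expect_equal(f[["x_std"]], sqrt(1.25))
  expect_equal(f[["x_iqr"]], 1.5)
  expect_equal(f[["x_mad"]], 1.0)
})

test_that("constant signals map to the degenerate conventions", {
  n <- 50
  s <- data.frame(t = seq_len(n) * 20, x = rep(1, n), y = rep(2, n),
                  z = rep(3, n))
  f <- time_domain_features(s)
  expect_equal(f[c("x_mean", "y_mean", "z_mean")],
               c(x_mean = 1, y_mean = 2, z_mean = 3))
  expect_equal(unname(f[c("x_variance", "x_iqr", "x_mad", "x_kurtosis",
                          "x_entropy_time", "corr_xy", "corr_xz", "corr_yz")]),
               rep(0, 8))
  expect_equal(unname(f[c("gravity_x", "gravity_y", "gravity_z")]), c(1, 2, 3))
  # orientation angles of the (1,2,3) gravity vector
  expect_equal(unname(f[c("orient_x", "orient_y", "orient_z")]),
               acos(c(1, 2, 3) / sqrt(14)))

  fd <- frequency_domain_features(s)
  expect_equal(unname(fd[c("x_energy", "x_entropy_freq")]), c(0, 0))
  expect_equal(fd[["x_mean_dc"]], 1)

  zero <- data.frame(t = 1:8 * 20, x = numeric(8), y = numeric(8),
                     z = numeric(8))
  expect_equal(unname(frequency_domain_features(zero)[c("x_energy",
                                                        "x_entropy_freq",
                                                        "x_mean_dc")]),
               c(0, 0, 0))
})

test_that("perfect linear dependence gives correlation 1", {
  set.seed(3)
  x <- rnorm(30)
  s <- data.frame(t = 1:30 * 20, x = x, y = 2 * x + 1, z = rnorm(30))
  expect_equal(time_domain_features(s)[["corr_xy"]], 1.0)
})

test_that("pure sinusoid concentrates spectral mass in two bins", {
  n <- 64
  x <- sin(2 * pi * 4 * (0:(n - 1)) / n)  # 4 full periods
  s <- data.frame(t = 0:(n - 1) * 20, x = x, y = x, z = x)
  f <- frequency_domain_features(s)
  expect_equal(f[["x_entropy_freq"]], log(2), tolerance = 1e-9)
  expect_equal(f[["x_energy"]], oracle_energy(x), tolerance = 1e-6)
})

test_that("windows below min_samples are invalid", {
  s <- data.frame(t = 1:3, x = 1:3, y = 1:3, z = 1:3)
  expect_null(time_domain_features(s))
  expect_null(frequency_domain_features(s))
  expect_equal(length(time_domain_features(s, min_samples = 3)), 33L)
})

test_that("all features match brute-force oracles on random windows", {
  set.seed(99)
  for (i in 1:40) {
    s <- random_window_samples(sample(5:80, 1))
    td <- time_domain_features(s)
    fd <- frequency_domain_features(s)
    for (axis in c("x", "y", "z")) {
      v <- s[[axis]]
      expect_equal(td[[paste0(axis, "_mean")]], mean(v), tolerance = 1e-9)
      expect_equal(td[[paste0(axis, "_median")]], median(v), tolerance = 1e-9)
      expect_equal(td[[paste0(axis, "_variance")]], oracle_pop_var(v),
                   tolerance = 1e-9)
      expect_equal(td[[paste0(axis, "_std")]], sqrt(oracle_pop_var(v)),
                   tolerance = 1e-9)
      expect_equal(td[[paste0(axis, "_iqr")]], oracle_iqr(v),
                   tolerance = 1e-9)
      expect_equal(td[[paste0(axis, "_mad")]], oracle_mad(v),
                   tolerance = 1e-9)
      expect_equal(td[[paste0(axis, "_kurtosis")]],
                   e1071::kurtosis(v, type = 1), tolerance = 1e-9)
      expect_equal(td[[paste0(axis, "_entropy_time")]],
                   oracle_entropy_time(v), tolerance = 1e-9)
      expect_equal(td[[paste0("gravity_", axis)]], oracle_gravity(v),
                   tolerance = 1e-9)
      expect_equal(fd[[paste0(axis, "_energy")]], oracle_energy(v),
                   tolerance = 1e-6)
      expect_equal(fd[[paste0(axis, "_entropy_freq")]],
                   oracle_entropy_freq(v), tolerance = 1e-6)
      expect_equal(fd[[paste0(axis, "_mean_dc")]], mean(v), tolerance = 1e-9)
    }
    expect_equal(td[["corr_xy"]], cor(s$x, s$y), tolerance = 1e-9)
    # Parseval with the DC-excluded convention: sum a^2 = N dc^2 + energy
    for (axis in c("x", "y", "z")) {
      v <- s[[axis]]
      expect_equal(sum(v^2),
                   length(v) * fd[[paste0(axis, "_mean_dc")]]^2 +
                     fd[[paste0(axis, "_energy")]],
                   tolerance = 1e-6)
    }
  }
})

test_that("feature invariants hold on random windows", {
  set.seed(123)
  for (i in 1:20) {
    s <- random_window_samples(sample(4:60, 1))
    f <- c(time_domain_features(s), frequency_domain_features(s))
    expect_true(all(is.finite(f)))
    expect_true(all(f[grep("variance|iqr|mad|entropy|energy", names(f))] >= 0))
    expect_true(all(abs(f[grep("corr", names(f))]) <= 1))
    expect_true(all(f[grep("orient", names(f))] >= 0 &
                      f[grep("orient", names(f))] <= pi))
  }
})

test_that("two-stream extraction concatenates left then right", {
  t <- seq(0, 8000, by = 20)
  set.seed(5)
  mk <- function() inertial_stream(t, rnorm(length(t)), rnorm(length(t)),
                                   9.81 + rnorm(length(t)))
  left <- mk()
  grid <- make_window_grid(0, 8000, 1000, 0.5)
  res <- extract_imu_features(left, left, grid)
  expect_equal(ncol(res$features), 84L)
  expect_equal(unname(res$features[, 1:42]), unname(res$features[, 43:84]))
  expect_equal(colnames(res$features),
               c(imu_feature_names("left_"), imu_feature_names("right_")))

  # 60 s session at 75% overlap -> 237 rows
  t60 <- seq(0, 60000, by = 20)
  s60 <- inertial_stream(t60, sin(t60 / 500), cos(t60 / 300), t60 * 0 + 9.81)
  g60 <- make_window_grid(0, 60000, 1000, 0.75)
  expect_equal(nrow(extract_imu_features(s60, s60, g60)$features), 237L)

  # a 5 s gap drops the windows inside it
  keep <- t < 2000 | t >= 7000
  gap <- inertial_stream(t[keep], sin(t[keep]), cos(t[keep]),
                         t[keep] * 0 + 9.81)
  res_gap <- extract_imu_features(gap, gap, grid)
  # no kept window lies fully inside the gap
  expect_false(any(res_gap$grid$start_ms >= 2000 & res_gap$grid$end_ms <= 7000))
  expect_lt(nrow(res_gap$features), nrow(grid))
})

test_that("feature extraction is deterministic", {
  set.seed(8)
  s <- random_window_samples(60)
  st <- inertial_stream(s$t, s$x, s$y, s$z)
  g <- make_window_grid(0, max(s$t), 400, 0.5)
  a <- extract_imu_features(st, st, g)
  b <- extract_imu_features(st, st, g)
  expect_identical(a, b)
})
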