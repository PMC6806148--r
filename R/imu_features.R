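#' @name imu-features
#' @title Windowed accelerometer features
#'
#' @description
#' Each 3-axis window is summarized by 42 features: per axis (x, y, z) the
#' time-domain statistics mean, median, standard deviation, variance,
#' inter-quartile range, median absolute deviation, excess kurtosis, value
#' entropy, and the frequency-domain statistics spectral energy, spectral
#' entropy and DC mean (11 x 3 = 33); plus the three cross-axis Pearson
#' correlations, a 3-vector gravity estimate from a first-order exponential
#' low-pass, and the three gravity-to-axis orientation angles.
#'
#' Conventions (all chosen so every entry is finite and unit-testable):
#' * variance/std use population normalization (divide by n);
#' * iqr is Q75 - Q25 with linear interpolation;
#' * mad is the raw median absolute deviation, `median(|a - median(a)|)`;
#' * kurtosis is Fisher excess kurtosis, 0 for a constant signal;
#' * value entropy is the Shannon entropy (natural log) of a 10-equal-width-
#'   bin histogram over the window's own `[min, max]` range, 0 when min = max;
#' * correlations are 0 when either axis is constant;
#' * the gravity filter is `g <- 0.9 g + 0.1 a`, initialized at the first
#'   sample; its final value is reported;
#' * orientation_i = `acos(g_i / ||g||)` in `[0, pi]`, 0 when `||g|| = 0`;
#' * with `X_k` the length-N DFT of one axis: `mean_dc = X_0 / N` (the
#'   arithmetic mean), `energy = sum_{k>=1} |X_k|^2 / N` (DC excluded), and
#'   spectral entropy is the Shannon entropy (natural log) of the normalized
#'   non-DC power spectrum, 0 when that spectrum is all zero.
NULL

AXIS_FEATURES <- c("mean", "median", "std", "variance", "iqr", "mad",
                   "kurtosis", "entropy_time", "energy", "entropy_freq",
                   "mean_dc")

#' Feature names of a 42-dimensional per-device vector
#' @param prefix Optional prefix (e.g. `"left_"`) prepended to every name.
#' @return Character vector of length 42.
#' @export
imu_feature_names <- function(prefix = "") {
  nm <- c(as.vector(t(outer(c("x", "y", "z"), AXIS_FEATURES, paste, sep = "_"))),
          "corr_xy", "corr_xz", "corr_yz",
          "gravity_x", "gravity_y", "gravity_z",
          "orient_x", "orient_y", "orient_z")
  paste0(prefix, nm)
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0L) return(0)
  -sum(p * log(p))
}

axis_time_features <- function(v, n_bins = 10L) {
  n <- length(v)
  m <- mean(v)
  med <- stats::median(v)
  variance <- sum((v - m)^2) / n
  std <- sqrt(variance)
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  mad <- stats::median(abs(v - med))
  if (variance == 0) {
    kurt <- 0
    ent <- 0
  } else {
    kurt <- sum((v - m)^4) / n / variance^2 - 3
    rng <- range(v)
    width <- (rng[2L] - rng[1L]) / n_bins
    bin <- pmin(floor((v - rng[1L]) / width) + 1L, n_bins)
    ent <- shannon_entropy(tabulate(bin, n_bins) / n)
  }
  c(mean = m, median = med, std = std, variance = variance, iqr = iqr,
    mad = mad, kurtosis = kurt, entropy_time = ent)
}

axis_freq_features <- function(v) {
  n <- length(v)
  X <- stats::fft(v)
  mean_dc <- Re(X[1L]) / n
  if (n == 1L) {
    return(c(energy = 0, entropy_freq = 0, mean_dc = mean_dc))
  }
  pow <- Mod(X[-1L])^2
  tot <- sum(pow)
  # non-DC power at round-off level relative to the total spectrum is
  # treated as an exactly zero spectrum (constant signal)
  if (tot <= (tot + Mod(X[1L])^2) * 1e-20) {
    return(c(energy = 0, entropy_freq = 0, mean_dc = mean_dc))
  }
  c(energy = tot / n, entropy_freq = shannon_entropy(pow / tot),
    mean_dc = mean_dc)
}

low_pass_gravity <- function(v, alpha = 0.9) {
  # g_1 = v_1; g_i = alpha g_{i-1} + (1 - alpha) v_i
  g <- stats::filter((1 - alpha) * v, alpha, method = "recursive",
                     init = v[1L])
  as.numeric(g[length(g)])
}

safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Time-domain features of one window
#'
#' @param samples Data frame with columns `x`, `y`, `z` (one window's
#'   acceleration samples in time order), as returned by [assign_samples()].
#' @param min_samples Minimum samples for a window to be valid (default 4).
#' @param gravity_alpha Exponential low-pass coefficient for the gravity
#'   estimate (default 0.9).
#' @return Named vector of the 33 time-domain entries (8 statistics per axis
#'   plus correlations, gravity and orientation), or `NULL` when the window
#'   has fewer than `min_samples` samples (invalid window).
#' @export
time_domain_features <- function(samples, min_samples = 4L,
                                 gravity_alpha = 0.9) {
  if (nrow(samples) < min_samples) return(NULL)
  ax <- lapply(samples[c("x", "y", "z")], axis_time_features)
  g <- vapply(samples[c("x", "y", "z")], low_pass_gravity, numeric(1),
              alpha = gravity_alpha)
  gn <- sqrt(sum(g^2))
  orient <- if (gn == 0) c(0, 0, 0) else acos(pmin(pmax(g / gn, -1), 1))
  out <- c(ax$x, ax$y, ax$z,
           corr_xy = safe_cor(samples$x, samples$y),
           corr_xz = safe_cor(samples$x, samples$z),
           corr_yz = safe_cor(samples$y, samples$z),
           gravity = unname(g), orient = unname(orient))
  names(out) <- c(as.vector(t(outer(c("x", "y", "z"),
                                    AXIS_FEATURES[1:8], paste, sep = "_"))),
                  "corr_xy", "corr_xz", "corr_yz",
                  "gravity_x", "gravity_y", "gravity_z",
                  "orient_x", "orient_y", "orient_z")
  out
}

#' Frequency-domain features of one window
#'
#' @inheritParams time_domain_features
#' @return Named vector of 9 entries (`energy`, `entropy_freq`, `mean_dc` per
#'   axis), or `NULL` for an invalid window.
#' @export
frequency_domain_features <- function(samples, min_samples = 4L) {
  if (nrow(samples) < min_samples) return(NULL)
  ax <- lapply(samples[c("x", "y", "z")], axis_freq_features)
  out <- c(ax$x, ax$y, ax$z)
  names(out) <- as.vector(t(outer(c("x", "y", "z"),
                                  AXIS_FEATURES[9:11], paste, sep = "_")))
  out
}

# Full 42-vector for one window, NULL if invalid.
imu_window_features <- function(samples, min_samples = 4L,
                                gravity_alpha = 0.9) {
  td <- time_domain_features(samples, min_samples, gravity_alpha)
  if (is.null(td)) return(NULL)
  fd <- frequency_domain_features(samples, min_samples)
  out <- c(td, fd)[imu_feature_names()]
  out
}

#' Windowed features of a left+right wrist pair
#'
#' Computes the 42-dimensional feature vector for every window of the grid in
#' both streams and concatenates them left-then-right into 84 columns. A
#' window with fewer than `min_samples` samples in either stream (sensor
#' drop-out, gaps) is invalid and its row is dropped.
#'
#' @param stream_left,stream_right Aligned [inertial_stream()]s on the
#'   unified timeline.
#' @param grid Window grid from [make_window_grid()].
#' @param min_samples Minimum samples per window per stream (default 4).
#' @param gravity_alpha Gravity low-pass coefficient (default 0.9).
#' @return List with `grid` (the rows of `grid` that produced features) and
#'   `features` (numeric matrix, one row per valid window, 84 named columns).
#' @export
extract_imu_features <- function(stream_left, stream_right, grid,
                                 min_samples = 4L, gravity_alpha = 0.9) {
  nm <- c(imu_feature_names("left_"), imu_feature_names("right_"))
  k <- nrow(grid)
  rows <- vector("list", k)
  keep <- logical(k)
  for (i in seq_len(k)) {
    w <- grid[i, ]
    fl <- imu_window_features(assign_samples(w, stream_left),
                              min_samples, gravity_alpha)
    if (is.null(fl)) next
    fr <- imu_window_features(assign_samples(w, stream_right),
                              min_samples, gravity_alpha)
    if (is.null(fr)) next
    rows[[i]] <- c(fl, fr)
    keep[i] <- TRUE
  }
  features <- do.call(rbind, rows[keep])
  if (is.null(features)) features <- matrix(numeric(0), 0L, length(nm))
  colnames(features) <- nm
  list(grid = grid[keep, , drop = FALSE], features = features)
}
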