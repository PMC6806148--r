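# Independent brute-force oracles, written from the statistical definitions
# and kept free of any package internals.

oracle_pop_var <- function(x) sum((x - sum(x) / length(x))^2) / length(x)

# type-7 quantile by explicit linear interpolation of the order statistics
oracle_quantile7 <- function(x, p) {
  s <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[min(lo + 2, length(x))] - s[lo + 1])
}

oracle_iqr <- function(x) oracle_quantile7(x, 0.75) - oracle_quantile7(x, 0.25)

oracle_mad <- function(x) median(abs(x - median(x)))

oracle_entropy_time <- function(x, n_bins = 10) {
  if (min(x) == max(x)) return(0)
  edges <- seq(min(x), max(x), length.out = n_bins + 1)
  counts <- integer(n_bins)
  for (v in x) {
    b <- which(v >= edges[-length(edges)] & (v < edges[-1] |
                 (v == edges[n_bins + 1] & seq_len(n_bins) == n_bins)))
    counts[b[length(b)]] <- counts[b[length(b)]] + 1
  }
  p <- counts[counts > 0] / length(x)
  -sum(p * log(p))
}

oracle_gravity <- function(x, alpha = 0.9) {
  g <- x[1]
  for (i in seq_along(x)[-1]) g <- alpha * g + (1 - alpha) * x[i]
  g
}

# direct O(N^2) DFT
oracle_dft <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k) {
    sum(x * exp(-2i * pi * k * (0:(n - 1)) / n))
  }, complex(1))
}

oracle_energy <- function(x) {
  X <- oracle_dft(x)
  sum(Mod(X[-1])^2) / length(x)
}

oracle_entropy_freq <- function(x) {
  X <- oracle_dft(x)
  pow <- Mod(X[-1])^2
  if (sum(pow) == 0) return(0)
  p <- pow / sum(pow)
  p <- p[p > 0]
  -sum(p * log(p))
}

# pixel-rasterization overlap oracle for integer-coordinate boxes
oracle_overlap_raster <- function(hand, obj) {
  px <- expand.grid(x = seq(obj$x_min, obj$x_max - 1),
                    y = seq(obj$y_min, obj$y_max - 1))
  inside <- px$x >= hand$x_min & px$x < hand$x_max &
    px$y >= hand$y_min & px$y < hand$y_max
  sum(inside) / nrow(px)
}

random_box <- function(max_dim = 100) {
  x0 <- sample(0:(max_dim - 2), 1)
  y0 <- sample(0:(max_dim - 2), 1)
  data.frame(x_min = x0, y_min = y0,
             x_max = x0 + sample(1:(max_dim - x0), 1),
             y_max = y0 + sample(1:(max_dim - y0), 1))
}

random_window_samples <- function(n = 50) {
  data.frame(t = seq(0, by = 20, length.out = n),
             x = rnorm(n, 0, 2), y = runif(n, -3, 3),
             z = 9.81 + rnorm(n, 0, 1))
}
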