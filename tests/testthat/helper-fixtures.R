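# Shared fixtures, all generated in code.

# Exactly periodic magnitude series whose peaks fall on sample points.
cos_series <- function(period = 50, n_cycles = 8, peak_at = 13) {
  t <- 0:(period * n_cycles - 1)
  1 + cos(2 * pi * (t - (peak_at - 1)) / period)
}

# 3D points moving on a unit circle in a tilted plane, angular step omega.
circle_series <- function(n, omega, seed = 1) {
  theta <- (0:(n - 1)) * omega
  flat <- cbind(cos(theta), sin(theta), 0)
  flat %*% t(random_rotation(seed))
}

# Seeded random walk in R^3 (generic position: no degenerate angles).
random_walk3 <- function(n, seed = 1, step = 1) {
  set.seed(seed)
  apply(matrix(rnorm(3 * n, sd = step), ncol = 3), 2, cumsum)
}

# A small jittered recording of smooth deterministic channels.
jittered_recording <- function(duration = 10, rate = 28.57, seed = 1,
                               freq = 1) {
  set.seed(seed)
  gaps <- pmax(rnorm(ceiling(duration * rate * 1.5), 1 / rate, 0.005),
               0.2 / rate)
  t <- cumsum(c(0, gaps))
  t <- t[t <= duration]
  a <- cbind(sin(2 * pi * freq * t), cos(2 * pi * freq * t), 9.8 + 0 * t)
  q <- cbind(cos(2 * pi * freq * t), 0.5 * sin(2 * pi * freq * t), 0 * t)
  imu_recording(t, a, q)
}

# Brute-force single angle per the vertex-chord definition.
angle_oracle <- function(x, m, t) {
  u <- x[t - m, ] - x[t, ]
  v <- x[t + m, ] - x[t, ]
  acos(min(1, max(-1, sum(u * v) / sqrt(sum(u^2)) / sqrt(sum(v^2)))))
}
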