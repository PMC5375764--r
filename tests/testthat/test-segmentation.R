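test_that("circular autocorrelation finds the fundamental period", {
  # brute-force oracle over every lag in the window
  aM <- 1 + sin(2 * pi * (0:(8 * 55 - 1)) / 55)
  n <- length(aM)
  x <- aM - mean(aM)
  lags <- 20:100
  r <- vapply(lags, function(g) sum(x * x[(seq_len(n) + g - 1) %% n + 1]),
              numeric(1))
  oracle <- lags[which.max(r)]
  expect_true(oracle %in% 54:56)
  expect_true(estimate_period(aM, 50) %in% 54:56)

  set.seed(14)
  expect_error(estimate_period(rnorm(400), 50), "not periodic")

  sub <- make_subject(1, seed = 3, cadence_range = c(1, 1))
  sim <- simulate_recording(sub, session_spec(duration = 20, seed = 5))
  ser <- resample(sim$recording, 50)
  expect_true(abs(estimate_period(ser$aM, 50) - 50) <= 1)
})

test_that("peak detection matches exhaustive neighbour comparison", {
  expect_false(any(find_peaks(1:20)))
  bump <- c(1, 2, 3, 4, 3, 2, 1)
  expect_equal(which(find_peaks(bump)), 4)
  # plateaus collapse to their leftmost sample
  expect_equal(which(find_peaks(c(0, 1, 1, 1, 0))), 2)

  set.seed(7)
  y <- rnorm(200)
  oracle <- vapply(2:199, function(t) y[t - 1] < y[t] && y[t] >= y[t + 1],
                   logical(1))
  expect_equal(find_peaks(y), c(FALSE, oracle, FALSE))
})

test_that("monotone arc lengths match per-step summation", {
  none <- monotone_segments(rep(2, 10), epsilon = 1, rate = 50)
  expect_equal(nrow(none), 0)

  desc <- seq(10, 10 - 5 * 0.5, by = -0.5)  # 5 steps of drop 0.5
  seg <- monotone_segments(desc, epsilon = 0, rate = 50)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$length, 5 * 0.5)
  expect_equal(seg$sign, -1L)

  v <- c(5, 3, 2, 1.5, 2.5, 4, 6)
  segs <- monotone_segments(v, epsilon = 2, rate = 50, min_len = 1)
  brute <- function(idx) sum(sqrt(diff(v)[idx]^2 + (2 / 50)^2))
  expect_equal(segs$length[1], brute(1:3))
  expect_equal(segs$length[2], brute(4:6))
  # short-run filtering
  wig <- c(5, 4, 3, 2, 2.5, 2, 1, 0.5, 1, 2, 3)
  segs2 <- monotone_segments(wig, epsilon = 0, rate = 50, min_len = 3)
  expect_true(any(!segs2$kept))
  expect_true(all((segs2$end - segs2$start)[segs2$kept] >= 3))
})

test_that("U-shape length sums the valley limbs left of a peak", {
  # symmetric valley: descend 4 steps of 1, ascend 4 steps of 1, peak on top
  y <- c(6, 5, 4, 3, 2, 3, 4, 5, 6, 5, 4)
  segs <- monotone_segments(y, epsilon = 0, rate = 50)
  expect_equal(u_shape_length_left(9, segs), 8)  # 2 * (4 steps of drop 1)
  # the first rising peak has no completed U on its left
  y2 <- c(1, 2, 3, 2, 1, 2, 3)
  segs2 <- monotone_segments(y2, epsilon = 0, rate = 50, min_len = 2)
  expect_equal(u_shape_length_left(3, segs2), 0)
})

test_that("the attenuated cycle's peak still carries the largest left U-shape", {
  fix <- attenuated_peak_series(period = 60, n_cycles = 6, cycle = 4)
  segs <- monotone_segments(fix$aM, epsilon = 0, rate = 50)
  weak <- fix$true_starts[4]
  peaks <- which(find_peaks(fix$aM))
  neighbours <- peaks[abs(peaks - weak) <= 30 & peaks != weak]
  lu_weak <- u_shape_length_left(weak, segs)
  for (p in neighbours) {
    expect_gte(lu_weak, u_shape_length_left(p, segs))
  }
})

test_that("candidate scoring ranks by height plus U-shape and sizes the set", {
  # two equal-height peaks; the second follows a much deeper valley
  y <- c(3, 4, 3.5, 3, 4, 3, 2, 1, 0, 2.5, 5 - 1, 2, 1)
  y[5] <- 4  # peak 1 at 5 (after shallow dip), peak 2 at 11 after deep valley
  y[11] <- 4
  sc <- suppressWarnings(
    score_candidates(y, period = 6, rate = 50, epsilon = 0, min_len = 1))
  expect_gt(sc$tau[11], sc$tau[5])
  expect_equal(sc$tau[3], 0)  # off-peak scores are zero

  # Nc = smallest integer strictly greater than 2N/period
  aM <- cos_series(period = 55, n_cycles = 8)[1:400]
  sc2 <- suppressWarnings(score_candidates(aM, period = 55, rate = 50))
  expect_equal(sc2$n_candidates, 15)  # floor(800/55) + 1

  # on a clean sinusoid every true peak is a candidate
  aM3 <- cos_series(period = 50, n_cycles = 8)
  sc3 <- suppressWarnings(score_candidates(aM3, period = 50, rate = 50))
  expect_setequal(sc3$candidates, seq(13, 363, by = 50))
})

test_that("segmentation recovers closed-form peak positions exactly", {
  aM <- cos_series(period = 50, n_cycles = 8, peak_at = 13)
  seg <- suppressWarnings(segment_gait(aM, 50))
  expect_equal(seg$period, 50)
  expect_equal(seg$starts, seq(13, 363, by = 50))
  expect_equal(diff(seg$starts), rep(50, 7))
  # perfectly periodic input: the grid fit reaches its fixed point fast
  expect_lte(seg$iterations, 3)
  expect_true(seg$grid_spacing >= 0.5 * seg$period &&
                seg$grid_spacing <= 1.5 * seg$period)
})

test_that("a weak peak survives segmentation through the periodicity grid", {
  fix <- attenuated_peak_series(period = 50, n_cycles = 8, cycle = 6,
                                factor = 0.6)
  seg <- suppressWarnings(segment_gait(fix$aM, 50))
  expect_equal(length(seg$starts), 8)
  expect_true(all(abs(seg$starts - fix$true_starts) <= 2))
})

test_that("segmentation is translation-equivariant", {
  fix <- attenuated_peak_series(period = 50, n_cycles = 8, cycle = NA)
  shift <- 17
  shifted <- c(fix$aM[(shift + 1):length(fix$aM)], fix$aM[1:shift])
  s1 <- suppressWarnings(segment_gait(fix$aM, 50))
  s2 <- suppressWarnings(segment_gait(shifted, 50))
  common <- intersect(s1$starts - shift, s2$starts)
  expect_gte(length(common), length(s1$starts) - 2)  # edge cycles aside
})

test_that("amplitude scaling with matched epsilon preserves the ranking", {
  fix <- attenuated_peak_series(period = 40, n_cycles = 6)
  alpha <- 7.3
  sc1 <- suppressWarnings(
    score_candidates(fix$aM, 40, 50, epsilon = 0.5, min_len = 2))
  sc2 <- suppressWarnings(
    score_candidates(alpha * fix$aM, 40, 50, epsilon = alpha * 0.5,
                     min_len = 2))
  expect_setequal(sc2$candidates, sc1$candidates)
  expect_equal(sc2$tau[sc2$candidates],
               alpha * sc1$tau[sc1$candidates], tolerance = 1e-9)
})

test_that("the local snap equals exhaustive within-radius search", {
  # <= 300 samples, <= 12 peaks: enumerate every assignment of grid points
  # to in-radius candidates and maximize the total penalized score
  fix <- attenuated_peak_series(period = 30, n_cycles = 9, cycle = 5)
  aM <- fix$aM[1:270]
  rate <- 50
  period <- estimate_period(aM, rate, lag_range = c(0.3, 2))
  epsilon <- 0.1 * sd(aM) * rate
  sc <- suppressWarnings(score_candidates(aM, period, rate, epsilon))
  seg <- suppressWarnings(segment_gait(aM, rate))
  expect_lte(length(which(find_peaks(aM))), 2 * 12)

  b <- seg$grid_offset; cc <- seg$grid_spacing
  grid <- as.integer(b + (0:(as.integer(length(aM) / cc) - 1)) * cc)
  grid <- grid[grid >= 1 & grid <= length(aM)]
  options_per_point <- lapply(grid, function(g) {
    cand <- sc$candidates[abs(sc$candidates - g) <= period / 4]
    if (!length(cand)) NA_integer_ else cand
  })
  # exhaustive product search (independent terms, still enumerated fully)
  combos <- expand.grid(options_per_point, KEEP.OUT.ATTRS = FALSE)
  total <- function(row) {
    s <- 0
    for (k in seq_along(row)) {
      t <- row[[k]]
      if (!is.na(t)) {
        s <- s + sc$tau[t] - (epsilon / rate) * abs(t - grid[k])
      }
    }
    s
  }
  scores <- apply(combos, 1, total)
  best <- combos[which.max(scores), ]
  best <- sort(unique(as.integer(best[!is.na(best)])))
  expect_equal(seg$starts, best)
})

test_that("degenerate inputs fail loudly", {
  expect_error(suppressWarnings(segment_gait(rep(1, 300), 50)))
})
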