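# Gait-cycle starting-position detection on the acceleration magnitude.
#
# The magnitude channel is orientation-free (rotations preserve norms), so a
# single scalar series drives segmentation no matter how the device was
# pocketed. Each cycle is assumed to start at a magnitude peak. Peaks are
# scored by their height plus the arc length of the U-shaped valley to their
# left, and a quasi-equally-spaced grid is fitted to the best-scoring peaks in
# two stages: a global grid fit (offset + spacing, iterated), then a local
# per-cycle snap with a distance penalty that keeps weak but periodic peaks.

#' Estimate the gait period by circular autocorrelation
#'
#' The lag maximizing the circular autocorrelation of the mean-removed
#' magnitude series, searched over a plausible cadence window. A truly
#' periodic series is equally self-similar at every multiple of its period,
#' so when an integer sub-multiple of the best lag scores nearly as high
#' (within `submultiple_tol` of the maximum) the sub-multiple is preferred;
#' this pins the estimate to the fundamental cycle rather than a double or
#' triple stride.
#'
#' @param aM Numeric magnitude series.
#' @param rate Sampling rate in Hz.
#' @param lag_range Lag search window in seconds, default `c(0.4, 2)`.
#' @param submultiple_tol Fraction of the peak autocorrelation a sub-multiple
#'   lag must reach to be preferred, default 0.9.
#' @param min_autocorr Minimum normalized circular autocorrelation
#'   (`r(lag) / r(0)`) the best lag must reach; below it the input is
#'   declared non-periodic. Default 0.2, far above what white noise attains
#'   at these series lengths and far below any walking signal.
#' @return Period estimate in samples.
#' @export
estimate_period <- function(aM, rate, lag_range = c(0.4, 2),
                            submultiple_tol = 0.9, min_autocorr = 0.2) {
  n <- length(aM)
  lags <- seq.int(max(2L, ceiling(lag_range[1] * rate)),
                  min(n - 1L, floor(lag_range[2] * rate)))
  if (!length(lags)) stop("series too short for the lag window", call. = FALSE)
  x <- aM - mean(aM)
  circ <- function(g) sum(x * x[(seq_len(n) + g - 1L) %% n + 1L])
  r <- vapply(lags, circ, numeric(1))
  r0 <- sum(x^2)
  if (r0 <= 0 || max(r) <= min_autocorr * r0) {
    stop("no circular-autocorrelation peak in the lag window: input not periodic",
         call. = FALSE)
  }
  g <- lags[which.max(r)]
  rmax <- max(r)
  repeat {
    divisors <- unique(as.integer(round(g / 2:4)))
    divisors <- divisors[divisors >= min(lags)]
    better <- divisors[vapply(divisors, function(d) {
      # allow +-1 sample around the rounded sub-multiple
      cand <- intersect((d - 1L):(d + 1L), lags)
      length(cand) && max(vapply(cand, circ, numeric(1))) >=
        submultiple_tol * rmax
    }, logical(1))]
    if (!length(better)) break
    d <- min(better)
    cand <- intersect((d - 1L):(d + 1L), lags)
    g <- cand[which.max(vapply(cand, circ, numeric(1)))]
  }
  g
}

#' Locate local maxima of a series
#'
#' A sample is a peak when its left neighbour is strictly smaller and its
#' right neighbour is not larger, which collapses plateaus to their leftmost
#' sample. Endpoints are never peaks.
#'
#' @param aM Numeric series.
#' @return Logical vector, `TRUE` at peaks.
#' @export
find_peaks <- function(aM) {
  n <- length(aM)
  p <- logical(n)
  if (n >= 3) {
    i <- 2:(n - 1)
    p[i] <- aM[i - 1] < aM[i] & aM[i] >= aM[i + 1]
  }
  p
}

#' Decompose a series into maximal monotone segments
#'
#' Each run of consecutive same-sign differences becomes one segment with an
#' arc length that treats the series as a planar curve: every step
#' contributes `sqrt(diff^2 + (epsilon/rate)^2)`, where `epsilon` converts
#' the unit time step into an equivalent amplitude. Segments spanning fewer
#' than `min_len` steps are flagged as too short to participate in U-shape
#' assembly.
#'
#' @param aM Numeric series.
#' @param epsilon Time-step equivalence coefficient (amplitude units per
#'   second); see [segmentation_config()].
#' @param rate Sampling rate in Hz.
#' @param min_len Minimum number of steps for a segment to be kept, default 3.
#' @return A data frame with columns `start`, `end` (1-based sample indices),
#'   `sign` (+1 increasing, -1 decreasing), `length` (arc length) and `kept`.
#' @export
monotone_segments <- function(aM, epsilon, rate, min_len = 3) {
  stopifnot(epsilon >= 0, rate > 0)
  d <- diff(aM)
  s <- sign(d)
  nz <- which(s != 0)
  if (!length(nz)) {
    return(data.frame(start = integer(), end = integer(), sign = integer(),
                      length = numeric(), kept = logical()))
  }
  # runs of constant nonzero sign; zero steps break runs
  brk <- c(TRUE, diff(nz) != 1L | s[nz[-1]] != s[nz[-length(nz)]])
  run_id <- cumsum(brk)
  step_len <- sqrt(d^2 + (epsilon / rate)^2)
  starts <- tapply(nz, run_id, min)
  ends <- tapply(nz, run_id, max) + 1L
  lens <- tapply(step_len[nz], run_id, sum)
  signs <- tapply(s[nz], run_id, `[`, 1L)
  out <- data.frame(start = as.integer(starts), end = as.integer(ends),
                    sign = as.integer(signs), length = as.numeric(lens))
  out$kept <- (out$end - out$start) >= min_len
  out
}

#' Arc length of the nearest U-shape left of a peak
#'
#' A U-shape is an adjacent decreasing-then-increasing pair of monotone
#' segments after short segments have been omitted; its length is the sum of
#' the two arc lengths. Omitting a short segment bridges its neighbours, so
#' consecutive kept segments of equal sign (a long limb chopped up by small
#' ripples) are merged before pairing. The nearest pair whose rising limb
#' ends at or before `t` is used; 0 when none exists.
#'
#' @param t 1-based peak index.
#' @param segments Result of [monotone_segments()].
#' @return Non-negative arc length.
#' @export
u_shape_length_left <- function(t, segments) {
  seg <- merge_kept_segments(segments)
  if (nrow(seg) < 2) return(0)
  best <- 0
  best_end <- -Inf
  for (i in seq_len(nrow(seg) - 1L)) {
    if (seg$sign[i] == -1L && seg$sign[i + 1L] == 1L &&
        seg$end[i + 1L] <= t && seg$end[i + 1L] > best_end) {
      best <- seg$length[i] + seg$length[i + 1L]
      best_end <- seg$end[i + 1L]
    }
  }
  best
}

# Kept segments with consecutive equal signs collapsed into one limb.
merge_kept_segments <- function(segments) {
  seg <- segments[segments$kept, , drop = FALSE]
  if (nrow(seg) < 2) return(seg)
  grp <- cumsum(c(TRUE, seg$sign[-1] != seg$sign[-nrow(seg)]))
  data.frame(start = as.integer(tapply(seg$start, grp, min)),
             end = as.integer(tapply(seg$end, grp, max)),
             sign = as.integer(tapply(seg$sign, grp, `[`, 1L)),
             length = as.numeric(tapply(seg$length, grp, sum)),
             kept = TRUE)
}

#' Score peaks and select starting-position candidates
#'
#' Each peak scores its magnitude plus the arc length of the U-shape to its
#' left; the `Nc` best-scoring peaks form the candidate set, where `Nc` is
#' the smallest integer strictly greater than `2 * N / period`. When fewer
#' peaks exist than `Nc`, all peaks are candidates (with a warning).
#'
#' @param aM Numeric magnitude series.
#' @param period Period estimate in samples.
#' @param rate Sampling rate in Hz.
#' @param epsilon Time-step equivalence coefficient; default
#'   `0.1 * sd(aM) * rate` so that `epsilon / rate` is a tenth of the
#'   series' spread.
#' @param min_len Minimum monotone-segment steps, default 3.
#' @return A list with `tau` (score vector, 0 off-peak), `candidates`
#'   (sorted candidate indices), `lU` (U-shape length at every sample, 0
#'   off-peak), `peaks` (logical), `segments` and `n_candidates`.
#' @export
score_candidates <- function(aM, period, rate,
                             epsilon = 0.1 * stats::sd(aM) * rate,
                             min_len = 3) {
  stopifnot(period > 0)
  n <- length(aM)
  peaks <- find_peaks(aM)
  segs <- monotone_segments(aM, epsilon, rate, min_len)
  lU <- numeric(n)
  tau <- numeric(n)
  idx <- which(peaks)
  for (t in idx) {
    lU[t] <- u_shape_length_left(t, segs)
    tau[t] <- aM[t] + lU[t]
  }
  nc <- floor(2 * n / period) + 1L
  if (length(idx) < nc) {
    warning(sprintf("only %d peaks available for %d candidate slots",
                    length(idx), nc))
    cand <- idx
  } else {
    cand <- idx[order(-tau[idx], idx)][seq_len(nc)]
  }
  list(tau = tau, candidates = sort(cand), lU = lU, peaks = peaks,
       segments = segs, n_candidates = nc)
}

#' Segmentation tuning parameters
#'
#' @param epsilon Time-step equivalence coefficient; `NULL` (default) means
#'   `0.1 * sd(aM) * rate`, i.e. one time step counts as a tenth of the
#'   series' standard deviation of amplitude.
#' @param min_len Minimum monotone-segment steps for U-shape assembly.
#' @param eps_term Grid-fit termination threshold in samples, default 0.5.
#' @param max_iter Iteration cap for the grid fit, default 20.
#' @param lag_range Period-search window in seconds.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(epsilon = NULL, min_len = 3, eps_term = 0.5,
                                max_iter = 20, lag_range = c(0.4, 2)) {
  structure(list(epsilon = epsilon, min_len = min_len, eps_term = eps_term,
                 max_iter = max_iter, lag_range = lag_range),
            class = "segmentation_config")
}

# Snap one grid index to the best candidate within `radius`. Ties in score
# break by smaller distance, then smaller index. Returns NA when no
# candidate lies within the radius.
greedy_snap <- function(grid_pos, candidates, score, radius, penalty = 0) {
  d <- abs(candidates - grid_pos)
  ok <- d <= radius
  if (!any(ok)) return(NA_integer_)
  cand <- candidates[ok]
  sc <- score[cand] - penalty * d[ok]
  ord <- order(-sc, d[ok], cand)
  cand[ord[1L]]
}

#' Detect gait-cycle starting positions
#'
#' Two-stage grid-based greedy fit to the scored peak candidates. Stage 1
#' fits an equally spaced grid: starting from offset 0 and spacing equal to
#' the period estimate, each grid index snaps to the best candidate within
#' half a period, then the spacing is re-estimated as the mean inter-snap
#' difference and the offset shifted by the mean residual, iterating until
#' both move by at most `eps_term` samples (iteration capped). Stage 2
#' releases the equal-spacing constraint: each final grid index snaps to the
#' best candidate within a quarter period under a score penalized by
#' `epsilon / rate` per sample of distance from the grid, so a weak but
#' periodic peak beats a strong aperiodic one.
#'
#' @param aM Numeric magnitude series (a buffer of at least ~4 s).
#' @param rate Sampling rate in Hz.
#' @param config A [segmentation_config()].
#' @param period Optional period override in samples; default estimated by
#'   [estimate_period()].
#' @return An object of class `segmentation_result`: `period`, `candidates`,
#'   `tau`, `grid_offset`, `grid_spacing`, `starts` (1-based sample
#'   indices), `n_cycles`, `iterations`.
#' @export
segment_gait <- function(aM, rate, config = segmentation_config(),
                         period = NULL) {
  n <- length(aM)
  if (is.null(period)) period <- estimate_period(aM, rate, config$lag_range)
  epsilon <- config$epsilon
  if (is.null(epsilon)) epsilon <- 0.1 * stats::sd(aM) * rate
  sc <- score_candidates(aM, period, rate, epsilon, config$min_len)
  cand <- sc$candidates
  if (!length(cand)) stop("no starting-position candidates found", call. = FALSE)

  # stage 1: iterate an equally spaced grid (offset b, spacing c)
  b <- 0; cc <- period; iter <- 0L
  repeat {
    iter <- iter + 1L
    nc <- as.integer(n / cc)
    grid <- as.integer(b + (0:(nc - 1L)) * cc)
    snap <- vapply(grid, greedy_snap, integer(1), candidates = cand,
                   score = sc$tau, radius = period / 2)
    ok <- which(!is.na(snap))
    if (length(ok) < 2) break
    # mean spacing per grid step: dividing each inter-snap difference by the
    # number of grid intervals it spans keeps unsnapped grid points from
    # inflating the estimate
    c_new <- sum(diff(snap[ok])) / sum(diff(ok))
    c_new <- min(max(c_new, 0.5 * period), 1.5 * period)
    b_new <- b + mean(snap[ok] - grid[ok])
    moved <- max(abs(b_new - b), abs(c_new - cc))
    b <- b_new; cc <- c_new
    if (moved <= config$eps_term || iter >= config$max_iter) break
  }

  # stage 2: local snap with distance penalty
  nc <- as.integer(n / cc)
  grid <- as.integer(b + (0:(nc - 1L)) * cc)
  grid <- grid[grid >= 1L & grid <= n]
  starts <- vapply(grid, greedy_snap, integer(1), candidates = cand,
                   score = sc$tau, radius = period / 4,
                   penalty = epsilon / rate)
  starts <- sort(unique(starts[!is.na(starts)]))
  structure(list(period = period, candidates = cand, tau = sc$tau,
                 grid_offset = b, grid_spacing = cc, starts = starts,
                 n_cycles = length(starts), iterations = iter),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> period %d samples, %d cycles, %d iterations\n",
              x$period, x$n_cycles, x$iterations))
  invisible(x)
}
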