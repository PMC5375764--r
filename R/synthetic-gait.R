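# Synthetic multi-subject gait simulator.
#
# Real gait acceleration is quasi-periodic at the cadence frequency with a
# dominant peak per cycle plus sub-dominant structure, and phones sample it
# irregularly because the OS multitasks. The simulator reproduces exactly
# those features -- per-subject harmonic signatures, timestamp jitter, sensor
# noise and a random per-session device orientation -- with full ground truth,
# so every downstream stage (resampling, segmentation, encoding,
# classification) is testable without any real dataset.

#' Create a synthetic walking subject
#'
#' A subject is a seeded bundle of per-axis harmonic signatures: each of the
#' six sensor channels is a sum of `n_harmonics` harmonics of the cadence
#' frequency with subject-specific amplitudes and phases. Distinct subjects
#' drawn from distinct `subject_id`s have distinct signatures with
#' overwhelming probability, which is what makes the cohort separable by a
#' classifier.
#'
#' @param subject_id Positive integer identity.
#' @param seed Integer cohort seed; the subject's private stream is derived
#'   from `(seed, subject_id)`.
#' @param n_harmonics Harmonic orders per axis (>= 2 so each cycle carries a
#'   dominant and sub-dominant peak). Default 4.
#' @param cadence_range Range (seconds) from which the gait-cycle duration is
#'   drawn. Default `c(0.9, 1.3)`, ordinary adult walking.
#' @param noise_sd Accelerometer noise standard deviation, m/s^2.
#' @param gyro_noise_sd Gyroscope noise standard deviation, rad/s.
#' @return An object of class `subject_spec`.
#' @export
make_subject <- function(subject_id, seed, n_harmonics = 4,
                         cadence_range = c(0.9, 1.3),
                         noise_sd = 0.15, gyro_noise_sd = 0.08) {
  stopifnot(subject_id >= 1, n_harmonics >= 2)
  with_seed(derive_seed(seed, subject_id), {
    cadence <- stats::runif(1, cadence_range[1], cadence_range[2])
    draw_axis <- function(base_amp, fundamental = NULL) {
      k <- seq_len(n_harmonics)
      amp <- stats::runif(n_harmonics, 0.3, 1) * base_amp / k
      # a dominant fundamental on request (heel-strike-like vertical impact)
      if (!is.null(fundamental)) {
        amp[1] <- stats::runif(1, fundamental[1], fundamental[2])
      }
      list(order = k, amplitude = amp,
           phase = stats::runif(n_harmonics, 0, 2 * pi))
    }
    # walking: the gravity-aligned axis carries a dominant once-per-cycle
    # impact; the lateral axes carry weaker subject-specific structure
    accel <- list(x = draw_axis(1.6), y = draw_axis(1.6),
                  z = draw_axis(1.6, fundamental = c(2.4, 3.4)))
    gyro <- lapply(c(x = 1, y = 2, z = 3), function(i) draw_axis(1.2))
    gravity <- c(0, 0, 9.81) + stats::rnorm(3, 0, 0.2)
    structure(
      list(subject_id = as.integer(subject_id),
           cadence_period = cadence,
           accel_harmonics = accel,
           gyro_harmonics = gyro,
           gravity_offset = gravity,
           noise_sd = noise_sd,
           gyro_noise_sd = gyro_noise_sd,
           seed = as.integer(seed)),
      class = "subject_spec")
  })
}

#' Describe a recording session
#'
#' A session fixes the acquisition conditions for one recording: duration,
#' jittered sampling statistics, and the similarity transform (orientation,
#' translation, scale) the casually worn device applies to the sensor frame.
#' A fresh session with a new orientation models re-pocketing the device
#' between days.
#'
#' @param duration Seconds, >= 4 so at least one segmentation buffer fits.
#' @param rate_mean,rate_sd Target sampling-rate mean and standard deviation
#'   in Hz. Defaults 28.57 and 4.17, typical of a multitasking phone OS.
#' @param orientation 3x3 rotation matrix (determinant +1); default drawn
#'   uniformly from the session seed.
#' @param translation 3-vector added to the acceleration channel.
#' @param scale Positive gain applied to both channels.
#' @param seed Integer session seed driving orientation, timestamp jitter and
#'   noise draws.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(duration, rate_mean = 28.57, rate_sd = 4.17,
                         orientation = NULL, translation = c(0, 0, 0),
                         scale = 1, seed = 1) {
  if (duration < 4) stop("session duration must be at least 4 s", call. = FALSE)
  stopifnot(rate_mean > 0, rate_sd >= 0, scale > 0, length(translation) == 3)
  if (is.null(orientation)) orientation <- random_rotation(derive_seed(seed, 101))
  if (!is_rotation_matrix(orientation)) {
    stop("`orientation` must be orthonormal with determinant +1", call. = FALSE)
  }
  structure(
    list(duration = duration, rate_mean = rate_mean, rate_sd = rate_sd,
         orientation = orientation, translation = as.numeric(translation),
         scale = scale, seed = as.integer(seed)),
    class = "session_spec")
}

# Evaluate the noiseless harmonic sum for one channel group at times t.
harmonic_series <- function(harmonics, t, period) {
  vapply(harmonics, function(h) {
    y <- numeric(length(t))
    for (i in seq_along(h$order)) {
      y <- y + h$amplitude[i] *
        sin(2 * pi * h$order[i] * t / period + h$phase[i])
    }
    y
  }, numeric(length(t)))
}

#' Apply a similarity (rotation-translation-scale) transform to 3-vectors
#'
#' @param series Numeric matrix, one 3-vector per row.
#' @param rotation 3x3 rotation matrix, orthonormal with determinant +1.
#' @param translation 3-vector added to every sample.
#' @param scale Positive scalar gain.
#' @return Matrix of the same shape with each row `x` mapped to
#'   `scale * rotation %*% x + translation`.
#' @export
apply_rigid_transform <- function(series, rotation, translation = c(0, 0, 0),
                                  scale = 1) {
  series <- as.matrix(series)
  stopifnot(ncol(series) == 3, length(translation) == 3)
  if (scale <= 0) stop("`scale` must be positive", call. = FALSE)
  if (!is_rotation_matrix(rotation)) {
    stop("`rotation` must be orthonormal with determinant +1", call. = FALSE)
  }
  out <- scale * series %*% t(rotation)
  sweep(out, 2, as.numeric(translation), `+`)
}

#' Simulate one inertial recording with ground truth
#'
#' Draws jittered timestamps (truncated-Gaussian inter-sample intervals,
#' floored at 0.2x the mean interval so time stays monotone), evaluates the
#' subject's harmonic signature plus gravity at those times, adds Gaussian
#' sensor noise, and applies the session's similarity transform: the
#' acceleration channel receives rotation, scale and translation; the
#' angular-velocity channel rotation and scale (a frame change does not
#' offset angular rates). Ground-truth cycle starts are the per-cycle global
#' maxima of the noiseless transformed acceleration magnitude.
#'
#' @param subject A `subject_spec`.
#' @param session A `session_spec` with
#'   `duration >= 2 * subject$cadence_period`.
#' @return A list with `recording` (an [imu_recording()]) and `starts`
#'   (ground-truth gait-cycle start times, seconds).
#' @export
simulate_recording <- function(subject, session) {
  stopifnot(inherits(subject, "subject_spec"), inherits(session, "session_spec"))
  if (session$duration < 2 * subject$cadence_period) {
    stop("session too short: need at least two gait cycles", call. = FALSE)
  }
  P <- subject$cadence_period
  with_seed(derive_seed(session$seed, subject$subject_id * 7 + 3), {
    mu <- 1 / session$rate_mean
    # delta method: sd of the interval that yields the requested rate sd
    sd_int <- session$rate_sd / session$rate_mean^2
    n_guess <- ceiling(session$duration / mu * 1.5) + 8
    gaps <- pmax(stats::rnorm(n_guess, mu, sd_int), 0.2 * mu)
    t <- cumsum(c(0, gaps))
    t <- t[t <= session$duration]

    accel <- harmonic_series(subject$accel_harmonics, t, P)
    accel <- sweep(accel, 2, subject$gravity_offset, `+`)
    gyro <- harmonic_series(subject$gyro_harmonics, t, P)
    if (subject$noise_sd > 0) {
      accel <- accel + matrix(stats::rnorm(length(accel), 0, subject$noise_sd),
                              ncol = 3)
    }
    if (subject$gyro_noise_sd > 0) {
      gyro <- gyro + matrix(stats::rnorm(length(gyro), 0, subject$gyro_noise_sd),
                            ncol = 3)
    }
    accel <- apply_rigid_transform(accel, session$orientation,
                                   session$translation, session$scale)
    gyro <- apply_rigid_transform(gyro, session$orientation, c(0, 0, 0),
                                  session$scale)

    # ground truth: phase of the global magnitude maximum of the noiseless
    # transformed signal over one cycle, then one start per cycle
    tg <- seq(0, P, length.out = 4097)[-4097]
    clean <- harmonic_series(subject$accel_harmonics, tg, P)
    clean <- sweep(clean, 2, subject$gravity_offset, `+`)
    clean <- apply_rigid_transform(clean, session$orientation,
                                   session$translation, session$scale)
    phase <- tg[which.max(sqrt(rowSums(clean^2)))]
    starts <- seq(phase, session$duration, by = P)

    list(recording = imu_recording(t, accel, gyro), starts = starts)
  })
}

#' Simulate a multi-session cohort
#'
#' Convenience wrapper generating `n_subjects` subjects and `n_sessions`
#' recordings per subject, each session with its own random device
#' orientation, as in repeated data-collection days.
#'
#' @param n_subjects Number of subjects.
#' @param n_sessions Sessions per subject.
#' @param duration Session length in seconds.
#' @param seed Cohort seed.
#' @param ... Further arguments passed to [make_subject()].
#' @return A list with `subjects` and `recordings`;
#'   `recordings[[i]][[j]]` is the [simulate_recording()] result for subject
#'   `i`, session `j`.
#' @export
simulate_cohort <- function(n_subjects, n_sessions = 1, duration = 60,
                            seed = 1, ...) {
  subjects <- lapply(seq_len(n_subjects), make_subject, seed = seed, ...)
  recordings <- lapply(seq_len(n_subjects), function(i) {
    lapply(seq_len(n_sessions), function(j) {
      ses <- session_spec(duration = duration,
                         seed = derive_seed(seed, i * 1000 + j))
      simulate_recording(subjects[[i]], ses)
    })
  })
  list(subjects = subjects, recordings = recordings)
}

#' Synthetic acceleration-magnitude fixture with one attenuated peak
#'
#' Builds an exactly periodic magnitude series whose cycles each carry a
#' dominant and a sub-dominant peak, then scales the oscillatory part of one
#' chosen cycle by `factor` so its dominant peak becomes "weak" -- the
#' robustness scenario where a segmentation that chases raw amplitude drops a
#' cycle but a periodicity-constrained one must not.
#'
#' @param period Cycle length in samples.
#' @param n_cycles Number of cycles.
#' @param cycle Which cycle (1-based) to attenuate; `NA` for none.
#' @param factor Attenuation of the oscillatory part, default 0.6.
#' @return A list with `aM` (numeric series of length `period * n_cycles`)
#'   and `true_starts` (1-based indices of the per-cycle dominant peaks).
#' @export
attenuated_peak_series <- function(period = 50, n_cycles = 8, cycle = 6,
                                   factor = 0.6) {
  stopifnot(period >= 8, n_cycles >= 2)
  n <- period * n_cycles
  t <- 0:(n - 1)
  osc <- sin(2 * pi * t / period) + 0.45 * sin(4 * pi * t / period + 0.9)
  amp <- rep(1, n)
  if (!is.na(cycle)) {
    stopifnot(cycle >= 1, cycle <= n_cycles)
    amp[t %/% period == (cycle - 1)] <- factor
  }
  aM <- 2 + amp * osc
  # dominant peak phase from one clean cycle
  one <- sin(2 * pi * 0:(period - 1) / period) +
    0.45 * sin(4 * pi * 0:(period - 1) / period + 0.9)
  phase <- which.max(one) - 1L
  list(aM = aM, true_starts = phase + period * 0:(n_cycles - 1) + 1L)
}

#' Write a recording as delimited text
#'
#' Columns `t, ax, ay, az, qx, qy, qz` with a header line, comma separator
#' and `.` decimal. If `starts` is given, a sidecar file `<path>.starts.txt`
#' is written with one ground-truth start time (seconds) per line.
#'
#' @param recording An [imu_recording()].
#' @param path Output file path.
#' @param starts Optional numeric vector of ground-truth start times.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, starts = NULL) {
  stopifnot(inherits(recording, "imu_recording"))
  df <- data.frame(t = recording$timestamps,
                   ax = recording$accel[, 1], ay = recording$accel[, 2],
                   az = recording$accel[, 3],
                   qx = recording$gyro[, 1], qy = recording$gyro[, 2],
                   qz = recording$gyro[, 3])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(starts)) {
    writeLines(format(starts, digits = 12, trim = TRUE),
               paste0(path, ".starts.txt"))
  }
  invisible(path)
}
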