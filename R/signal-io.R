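# Reading raw IMU logs and preparing uniform buffers.

#' Construct a validated inertial recording
#'
#' @param timestamps Strictly increasing sample times in seconds.
#' @param accel,gyro Numeric matrices with one 3-vector per row
#'   (accelerometer in m/s^2, gyroscope in rad/s), same number of rows as
#'   `timestamps`.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(timestamps, accel, gyro) {
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  n <- length(timestamps)
  if (nrow(accel) != n || nrow(gyro) != n || ncol(accel) != 3 || ncol(gyro) != 3) {
    stop("timestamps, accel and gyro must have matching lengths (n x 3)",
         call. = FALSE)
  }
  if (n >= 2) {
    bad <- which(diff(timestamps) <= 0)
    if (length(bad)) {
      stop(sprintf("timestamps not strictly increasing at sample %d", bad[1] + 1),
           call. = FALSE)
    }
  }
  structure(list(timestamps = as.numeric(timestamps),
                 accel = unname(accel), gyro = unname(gyro)),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %d samples over %.2f s (mean rate %.2f Hz)\n",
              length(x$timestamps), diff(range(x$timestamps)),
              (length(x$timestamps) - 1) / diff(range(x$timestamps))))
  invisible(x)
}

#' Load a recording from delimited text
#'
#' Expects the schema written by [write_recording()]: header line with
#' columns `t, ax, ay, az, qx, qy, qz`, comma-separated, `.` decimal. Foreign
#' layouts are handled through `mapping`, a named list (or path to a YAML
#' file containing one) mapping each standard name to the foreign column
#' name, e.g. `list(t = "timestamp", ax = "accX", ...)`.
#'
#' @param path File to read.
#' @param mapping Optional column mapping, named list or YAML file path.
#' @return An [imu_recording()]. Missing columns, non-numeric rows and
#'   non-increasing timestamps raise an error naming the offending column or
#'   line.
#' @export
load_recording <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  std <- c("t", "ax", "ay", "az", "qx", "qy", "qz")
  if (!is.null(mapping)) {
    if (is.character(mapping) && length(mapping) == 1L) {
      mapping <- yaml::read_yaml(mapping)
    }
    missing_map <- setdiff(std, names(mapping))
    if (length(missing_map)) {
      stop("column mapping lacks entries for: ",
           paste(missing_map, collapse = ", "), call. = FALSE)
    }
    cols <- unlist(mapping[std])
  } else {
    cols <- std
  }
  absent <- setdiff(cols, names(df))
  if (length(absent)) {
    stop("missing columns in ", path, ": ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  vals <- lapply(cols, function(cn) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn)) {
        stop(sprintf("non-numeric value in column '%s' at line %d of %s",
                     cn, which(is.na(vn))[1] + 1L, path), call. = FALSE)
      }
      v <- vn
    }
    v
  })
  names(vals) <- std
  bad <- which(diff(vals$t) <= 0)
  if (length(bad)) {
    stop(sprintf("timestamps not increasing at line %d of %s", bad[1] + 2L, path),
         call. = FALSE)
  }
  imu_recording(vals$t, cbind(vals$ax, vals$ay, vals$az),
                cbind(vals$qx, vals$qy, vals$qz))
}

#' Elementwise Euclidean magnitude of a triaxial series
#'
#' @param a Numeric matrix with one 3-vector per row.
#' @return Non-negative numeric vector of per-sample norms.
#' @export
magnitude <- function(a) {
  a <- as.matrix(a)
  sqrt(rowSums(a^2))
}

#' Resample a recording onto a uniform grid by cubic spline
#'
#' Each of the six channels is interpolated independently with a cubic
#' spline (Forsythe-Malcolm-Moler end conditions, which reproduce cubic
#' polynomials exactly) and evaluated on a uniform grid anchored at the first
#' timestamp, so no extrapolation occurs. The acceleration magnitude is
#' computed after resampling.
#'
#' @param recording An [imu_recording()] with at least 4 samples.
#' @param rate Target rate in Hz, default 50.
#' @return An object of class `uniform_series` with fields `rate`, `a`
#'   (n x 3 acceleration), `q` (n x 3 angular velocity), `aM` (magnitude
#'   series), `n` (sample count) and `l` (buffer span `n / rate`, seconds).
#' @export
resample <- function(recording, rate = 50) {
  stopifnot(inherits(recording, "imu_recording"))
  if (rate <= 0) stop("`rate` must be positive", call. = FALSE)
  t <- recording$timestamps
  if (length(t) < 4) {
    stop("need at least 4 samples for cubic-spline resampling", call. = FALSE)
  }
  grid <- seq(t[1], t[length(t)], by = 1 / rate)
  ch <- function(y) stats::spline(t, y, xout = grid, method = "fmm")$y
  a <- cbind(ch(recording$accel[, 1]), ch(recording$accel[, 2]),
             ch(recording$accel[, 3]))
  q <- cbind(ch(recording$gyro[, 1]), ch(recording$gyro[, 2]),
             ch(recording$gyro[, 3]))
  uniform_series(rate, a, q, t0 = t[1])
}

#' Construct a uniform series container
#'
#' @param rate Sampling rate in Hz.
#' @param a,q n x 3 acceleration and angular-velocity matrices.
#' @param t0 Time of the first sample (seconds), default 0.
#' @return An object of class `uniform_series`; the magnitude channel `aM`
#'   is computed from `a`.
#' @export
uniform_series <- function(rate, a, q, t0 = 0) {
  a <- as.matrix(a); q <- as.matrix(q)
  stopifnot(nrow(a) == nrow(q), ncol(a) == 3, ncol(q) == 3, rate > 0)
  structure(list(rate = rate, a = a, q = q, aM = magnitude(a),
                 n = nrow(a), l = nrow(a) / rate, t0 = t0),
            class = "uniform_series")
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %d samples at %g Hz (%.2f s)\n", x$n, x$rate, x$l))
  invisible(x)
}

#' Cut a uniform series into fixed-length buffers
#'
#' Contiguous windows of `span * rate` samples taken every `hop` seconds;
#' a final partial window is dropped. A series shorter than one window
#' yields an empty list.
#'
#' @param series A `uniform_series`.
#' @param span Window length in seconds (default 4, the shortest buffer the
#'   segmentation stage accepts).
#' @param hop Hop between window starts in seconds; default `span`
#'   (non-overlapping).
#' @return List of `uniform_series` windows.
#' @export
buffer_windows <- function(series, span = 4, hop = span) {
  stopifnot(inherits(series, "uniform_series"), span > 0, hop > 0)
  N <- as.integer(round(span * series$rate))
  step <- as.integer(round(hop * series$rate))
  if (series$n < N) return(list())
  starts <- seq.int(1L, series$n - N + 1L, by = step)
  lapply(starts, function(s) {
    idx <- s:(s + N - 1L)
    uniform_series(series$rate, series$a[idx, , drop = FALSE],
                   series$q[idx, , drop = FALSE],
                   t0 = series$t0 + (s - 1L) / series$rate)
  })
}
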