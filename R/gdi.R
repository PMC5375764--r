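# Angle Embedded Gait Dynamic Images.
#
# A triaxial series is read as a polyline in R^3. For delay m and time t the
# meta-feature is the angle at vertex x(t) between the chords to x(t-m) and
# x(t+m). Angles survive any similarity transform of the frame (rotation,
# translation, uniform scaling), so the image built from them is identical no
# matter how the device was oriented -- unlike the inner-product (GDI)
# baseline, which a translation already breaks.

#' Time-delay angle feature
#'
#' Angle at vertex `x[t, ]` between the chords to `x[t - m, ]` and
#' `x[t + m, ]`, via the arc-cosine of the normalized inner product with the
#' cosine clipped to `[-1, 1]`. When either chord is shorter than `tol` the
#' angle is undefined; 0 is returned with attribute `degenerate = TRUE`.
#'
#' @param x Numeric matrix, one 3-vector per row.
#' @param m Delay in samples, `0 < m < nrow(x) / 2`.
#' @param t 1-based vertex index with `m < t <= nrow(x) - m`.
#' @param tol Degeneracy tolerance on chord norms.
#' @return Angle in radians, in `[0, pi]`.
#' @export
angle_feature <- function(x, m, t, tol = 1e-12) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(m >= 1, m < n / 2, t > m, t <= n - m)
  u <- x[t - m, ] - x[t, ]
  v <- x[t + m, ] - x[t, ]
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < tol || nv < tol) {
    return(structure(0, degenerate = TRUE))
  }
  structure(acos(min(1, max(-1, sum(u * v) / (nu * nv)))), degenerate = FALSE)
}

#' Generate one AE-GDI channel
#'
#' An `Nh x Nw` matrix whose entry `(j, i)` is the angle feature at delay
#' `j` and vertex `start + i - 1`: row `j` is the delay-`j` angle series
#' over one window aligned to a gait-cycle start. All referenced samples
#' must exist, i.e. `start > Nh` and `start + Nw - 1 + Nh <= nrow(x)`;
#' otherwise `NULL` is returned (the cycle is skipped) with a message.
#'
#' @param x Numeric matrix, one 3-vector per row.
#' @param start 1-based gait-cycle starting index.
#' @param Nw Window width in samples, default 64.
#' @param Nh Maximum time delay (image height), default 32.
#' @param source Channel provenance, `"accel"` or `"gyro"`.
#' @return Matrix with attributes `start`, `source` and `degenerate` (a
#'   logical mask of undefined-angle pixels, which are set to 0), or `NULL`
#'   when the margins do not fit.
#' @export
generate_aegdi <- function(x, start, Nw = 64, Nh = 32, source = "accel") {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(Nw >= 1, Nh >= 1, Nh < n / 2)
  if (start - Nh < 1 || start + Nw - 1 + Nh > n) {
    message(sprintf(
      "skipping cycle at %d: needs samples %d..%d but series has 1..%d",
      start, start - Nh, start + Nw - 1 + Nh, n))
    return(NULL)
  }
  ts <- start + 0:(Nw - 1L)
  px <- matrix(0, Nh, Nw)
  degen <- matrix(FALSE, Nh, Nw)
  for (j in seq_len(Nh)) {
    u <- x[ts - j, , drop = FALSE] - x[ts, , drop = FALSE]
    v <- x[ts + j, , drop = FALSE] - x[ts, , drop = FALSE]
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    bad <- nu < 1e-12 | nv < 1e-12
    cosang <- rowSums(u * v) / pmax(nu * nv, 1e-300)
    ang <- acos(pmin(1, pmax(-1, cosang)))
    ang[bad] <- 0
    px[j, ] <- ang
    degen[j, ] <- bad
  }
  structure(px, start = start, source = source, degenerate = degen)
}

#' Generate the GDI baseline encoding
#'
#' The predecessor encoding: entry `(j, i)` is the plain inner product
#' between `x[start + i - 1, ]` and the sample `j` later. Rotation-invariant
#' but not translation- or scale-invariant.
#'
#' @inheritParams generate_aegdi
#' @return Matrix with attributes `start` and `source`, or `NULL` when the
#'   margin does not fit.
#' @export
generate_gdi <- function(x, start, Nw = 64, Nh = 32, source = "accel") {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(Nw >= 1, Nh >= 1)
  if (start < 1 || start + Nw - 1 + Nh > n) {
    message(sprintf("skipping cycle at %d: window exceeds series", start))
    return(NULL)
  }
  ts <- start + 0:(Nw - 1L)
  px <- matrix(0, Nh, Nw)
  for (j in seq_len(Nh)) {
    px[j, ] <- rowSums(x[ts, , drop = FALSE] * x[ts + j, , drop = FALSE])
  }
  structure(px, start = start, source = source)
}

#' Stack acceleration and angular-velocity images into one multi-channel AE-GDI
#'
#' Channels are stored in canonical order (acceleration first, angular
#' velocity second) regardless of argument order, using the `source`
#' attribute set by [generate_aegdi()].
#'
#' @param gdi1 AE-GDI matrix (from the accelerometer unless tagged otherwise).
#' @param gdi2 Optional second AE-GDI matrix with the same dimensions and
#'   start index.
#' @return An `Nh x Nw x Nl` array of class `aegdi` with `Nl` 1 or 2 and
#'   attributes `start` and `channels`.
#' @export
assemble_channels <- function(gdi1, gdi2 = NULL) {
  src1 <- attr(gdi1, "source") %||% "accel"
  if (is.null(gdi2)) {
    out <- array(gdi1, c(nrow(gdi1), ncol(gdi1), 1L))
    chans <- src1
  } else {
    if (!all(dim(gdi1) == dim(gdi2))) {
      stop("channel shape mismatch", call. = FALSE)
    }
    s1 <- attr(gdi1, "start"); s2 <- attr(gdi2, "start")
    if (!is.null(s1) && !is.null(s2) && s1 != s2) {
      stop("channels must share the same start index", call. = FALSE)
    }
    src2 <- attr(gdi2, "source") %||% "gyro"
    if (src1 == "gyro" && src2 == "accel") {
      tmp <- gdi1; gdi1 <- gdi2; gdi2 <- tmp
      src1 <- "accel"; src2 <- "gyro"
    }
    out <- array(c(gdi1, gdi2), c(nrow(gdi1), ncol(gdi1), 2L))
    chans <- c(src1, src2)
  }
  structure(out, start = attr(gdi1, "start"), channels = chans,
            class = "aegdi")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Encode every detected gait cycle of a uniform series
#'
#' Runs [generate_aegdi()] at each starting index, optionally on both
#' channels, skipping cycles whose margins fall outside the buffer.
#'
#' @param series A [uniform_series()].
#' @param starts 1-based starting indices (e.g. from [segment_gait()]).
#' @param Nw,Nh Image width and height, defaults 64 and 32.
#' @param channels `"a"` (acceleration only) or `"aq"` (both).
#' @return A list with `x`, an `Nh x Nw x Nl x count` array, and `starts`,
#'   the indices actually encoded.
#' @export
encode_cycles <- function(series, starts, Nw = 64, Nh = 32, channels = "aq") {
  stopifnot(inherits(series, "uniform_series"), channels %in% c("a", "aq"))
  imgs <- list(); kept <- integer()
  for (s in starts) {
    ga <- suppressMessages(generate_aegdi(series$a, s, Nw, Nh, "accel"))
    if (is.null(ga)) next
    if (channels == "aq") {
      gq <- suppressMessages(generate_aegdi(series$q, s, Nw, Nh, "gyro"))
      if (is.null(gq)) next
      imgs[[length(imgs) + 1L]] <- assemble_channels(ga, gq)
    } else {
      imgs[[length(imgs) + 1L]] <- assemble_channels(ga)
    }
    kept <- c(kept, s)
  }
  if (!length(imgs)) {
    return(list(x = array(0, c(Nh, Nw, if (channels == "aq") 2L else 1L, 0L)),
                starts = integer()))
  }
  nl <- dim(imgs[[1]])[3]
  x <- array(0, c(Nh, Nw, nl, length(imgs)))
  for (i in seq_along(imgs)) x[, , , i] <- imgs[[i]]
  list(x = x, starts = kept)
}

#' Overlap-window baseline segmentation
#'
#' Fixed windows ignoring gait periodicity: starts every
#' `(window - overlap)` seconds while a full `window` fits.
#'
#' @param series_len Series length in samples.
#' @param rate Sampling rate in Hz.
#' @param window Window length in seconds, default 1.28.
#' @param overlap Overlap in seconds, default 0.5 (must be < `window`).
#' @return Integer vector of 1-based start indices (possibly empty).
#' @export
overlap_window_starts <- function(series_len, rate, window = 1.28,
                                  overlap = 0.5) {
  stopifnot(window > overlap, overlap >= 0)
  w <- as.integer(round(window * rate))
  hop <- as.integer(round((window - overlap) * rate))
  if (series_len < w) return(integer())
  seq.int(1L, series_len - w + 1L, by = hop)
}

#' Persist an AE-GDI batch
#'
#' Writes the pixel array with its metadata (starts, subject, session, rate,
#' image geometry) as an RDS file plus a human-readable JSON sidecar
#' (`<path>.json`) recording everything but the pixels.
#'
#' @param batch List with at least `x` (the `Nh x Nw x Nl x count` array)
#'   and `starts`, as produced by [encode_cycles()]; extra fields (e.g.
#'   `subject`, `session`, `rate`) are kept.
#' @param path Output path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
save_gdi_batch <- function(batch, path) {
  stopifnot(is.list(batch), !is.null(batch$x))
  saveRDS(batch, path)
  meta <- Filter(is.atomic, batch[setdiff(names(batch), "x")])
  meta$dim <- dim(batch$x)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load an AE-GDI batch written by [save_gdi_batch()]
#' @param path Path to the RDS file.
#' @return The batch list.
#' @export
load_gdi_batch <- function(path) readRDS(path)
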