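#' @keywords internal
"_PACKAGE"

# Run expr under a local RNG state seeded with `seed`, restoring the caller's
# stream afterwards. All stochastic code in the package funnels through this so
# that results are pure functions of (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream index, staying within
# the 32-bit integer range R requires.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483647
}

is_rotation_matrix <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) < tol &&
    abs(det(R) - 1) < tol
}

#' Draw a uniformly random 3D rotation matrix
#'
#' Used by the synthetic session generator to model a device dropped into a
#' pocket with arbitrary orientation. The rotation is drawn by QR
#' orthogonalisation of a Gaussian matrix with the sign convention fixed so
#' the result is deterministic in the seed, then reflected if needed to land
#' in SO(3).
#'
#' @param seed Integer seed.
#' @return A 3x3 orthonormal matrix with determinant +1.
#' @export
random_rotation <- function(seed) {
  with_seed(seed, {
    A <- matrix(stats::rnorm(9), 3, 3)
    qr_ <- qr(A)
    Q <- qr.Q(qr_)
    Q <- Q %*% diag(sign(diag(qr.R(qr_))))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
  })
}
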