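#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a base seed and integer tags
#'
#' All stochastic stages of the package draw from independent, reproducible
#' RNG streams.  Streams are identified by a base seed plus a short sequence
#' of integer tags (subject index, class index, repetition, fold, ...), mixed
#' through a linear-congruential hash into a 31-bit seed.
#'
#' @param ... integers (base seed first, then stream tags).
#' @return a single integer seed in `[0, 2^31)`.
#' @export
mix_seed <- function(...) {
  v <- as.numeric(c(...))
  if (any(!is.finite(v))) stop("seed components must be finite numbers")
  x <- 104729
  for (u in v) {
    x <- (x * 69069 + (abs(u) %% 1e9) * 7919 + 17) %% 2147483629
  }
  as.integer(x)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Thin wrapper over [withr::with_seed()] so package code never leaks RNG
#' state into the caller's session.
#' @keywords internal
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' A smooth standardized random curve
#'
#' Gaussian values at equally spaced knots, interpolated by a natural cubic
#' spline, then centered and scaled to unit standard deviation.  Used both
#' for class templates' low-frequency structure and for subject/repetition
#' perturbations, so that perturbation magnitudes stated as standard
#' deviations are exact by construction.
#'
#' @param len output length.
#' @param n_knots number of spline knots (>= 2).
#' @param seed integer seed.
#' @return numeric vector of length `len` with mean 0 and sd 1 (or all zeros
#'   in the degenerate constant case).
#' @keywords internal
smooth_curve <- function(len, n_knots, seed) {
  stopifnot(len >= 2, n_knots >= 2)
  y <- with_seed(seed, {
    kx <- seq(1, len, length.out = n_knots)
    ky <- stats::rnorm(n_knots)
    stats::spline(kx, ky, xout = seq_len(len))$y
  })
  s <- stats::sd(y)
  if (s < 1e-12) return(rep(0, len))
  (y - mean(y)) / s
}

#' Rotation matrix from axis and angle (Rodrigues form)
#'
#' Right-handed rotation by `angle_deg` degrees about `axis`.
#' @param axis numeric 3-vector (need not be normalized, must be nonzero).
#' @param angle_deg rotation angle in degrees.
#' @return a 3 x 3 orthonormal matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  stopifnot(length(axis) == 3)
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis must be a nonzero vector")
  k <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, k[3], -k[2],
                -k[3], 0, k[1],
                k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
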