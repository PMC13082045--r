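# Shared numeric helpers. Internal units are SI + radians everywhere;
# conversions happen only at I/O boundaries.

GRAVITY <- 9.80665

#' Smooth positive part
#'
#' `smooth_pos(x, eps)` approximates `max(x, 0)` with the C1-smooth form
#' `(x + sqrt(x^2 + eps^2)) / 2`. Used wherever a force law must be
#' differentiable across a contact/engagement boundary.
#'
#' @param x numeric vector.
#' @param eps smoothing half-width (same units as `x`).
#' @return numeric vector, >= 0, converging to `pmax(x, 0)` as `eps -> 0`.
#' @keywords internal
smooth_pos <- function(x, eps = 1e-4) {
  (x + sqrt(x * x + eps * eps)) / 2
}

# 2-D rotation of row-wise vectors: vx, vy rotated by theta (all vectors)
rot2 <- function(theta, vx, vy) {
  ct <- cos(theta); st <- sin(theta)
  list(x = ct * vx - st * vy, y = st * vx + ct * vy)
}

# perpendicular (z x v) of planar vectors
perp2 <- function(vx, vy) list(x = -vy, y = vx)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# trapezoid weights for a (possibly non-uniform) time grid
trapz_weights <- function(t) {
  n <- length(t)
  if (n < 2) stopf("time grid needs at least 2 points")
  w <- numeric(n)
  dt <- diff(t)
  w[1] <- dt[1] / 2
  w[n] <- dt[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dt[-1] + dt[-(n - 1)]) / 2
  w
}

#' Deterministic child seed for a named random stream
#'
#' Derives an integer seed (below 2^31) from a master seed and a stream
#' label, so independent generators can be driven from one user seed
#' without sharing their random streams.
#'
#' @param seed master integer seed.
#' @param stream character stream label.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# periodic cubic interpolation of columns of a matrix sampled on t (last
# row = first row assumed equivalent modulo the period)
periodic_splinefun <- function(t, y) {
  stats::splinefun(t, y, method = "periodic")
}
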