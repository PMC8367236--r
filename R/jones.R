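# Jones calculus for linear retarders.
#
# The whole compensation chain is built from one primitive: the Jones
# matrix of a linear retarder with retardation delta and (slow) axis
# orientation theta,
#
#   J(delta, theta) = | c^2 + s^2 e     c s (1 - e) |
#                     | c s (1 - e)     c^2 e + s^2 |
#
# with c = cos(theta), s = sin(theta), e = exp(-i delta).  J is unitary
# and symmetric, and J(-delta, theta) is its inverse, which is what
# makes numerical compensation of anterior birefringence possible.

#' Jones matrix of a linear retarder
#'
#' @param delta retardation of the retarder.
#' @param theta axis orientation of the retarder.
#' @param degrees logical; interpret `delta` and `theta` in degrees
#'   (default) or radians.
#' @return a 2x2 complex matrix; unitary and symmetric.
#' @details The matrix satisfies the compensation identity
#'   `jones_linear_retarder(delta, theta) %*%
#'    jones_linear_retarder(-delta, theta) == diag(2)` for all angles.
#' @export
#' @examples
#' jones_linear_retarder(0, 37)           # identity
#' jones_linear_retarder(90, 45)          # quarter-wave plate at 45 degrees
jones_linear_retarder <- function(delta, theta, degrees = TRUE) {
  stopifnot_finite(delta, "delta")
  stopifnot_finite(theta, "theta")
  stopifnot(length(delta) == 1L, length(theta) == 1L)
  if (degrees) {
    delta <- deg2rad(delta)
    theta <- deg2rad(theta)
  }
  e <- exp(-1i * delta)
  cc <- cos(theta)
  ss <- sin(theta)
  off <- cc * ss * (1 - e)
  matrix(c(cc^2 + ss^2 * e, off, off, cc^2 * e + ss^2), 2L, 2L)
}

#' Jones matrix of the quarter-wave plate of the instrument model
#'
#' The instrument converts the vertically polarized input beam
#' \eqn{(0, 1)^T} into circular polarization with a quarter-wave plate
#' oriented at 45 degrees; the backscattered beam passes the same plate
#' again on its way to the polarization-sensitive detection unit.
#'
#' @param theta plate orientation in degrees (default 45).
#' @return a 2x2 complex matrix.
#' @export
jones_qwp <- function(theta = 45) {
  jones_linear_retarder(90, theta)
}

# Vertically polarized input state of the instrument.
jones_input_state <- function() c(0 + 0i, 1 + 0i)

# ---- vectorized component arithmetic -------------------------------------
#
# For volume work the 2x2 matrices are carried as lists of four equally
# shaped component arrays (m11, m12, m21, m22) so that whole B-scans are
# multiplied elementwise without voxel loops.

jv_retarder <- function(delta, theta) {
  e <- exp(-1i * delta)
  cc <- cos(theta)
  ss <- sin(theta)
  off <- cc * ss * (1 - e)
  list(m11 = cc^2 + ss^2 * e, m12 = off, m21 = off, m22 = cc^2 * e + ss^2)
}

jv_const <- function(J, template = NULL) {
  out <- list(m11 = J[1L, 1L], m12 = J[1L, 2L], m21 = J[2L, 1L], m22 = J[2L, 2L])
  if (!is.null(template)) out <- lapply(out, function(x) array(x, dim(template)))
  out
}

jv_mul <- function(a, b) {
  list(m11 = a$m11 * b$m11 + a$m12 * b$m21,
       m12 = a$m11 * b$m12 + a$m12 * b$m22,
       m21 = a$m21 * b$m11 + a$m22 * b$m21,
       m22 = a$m21 * b$m12 + a$m22 * b$m22)
}

jv_t <- function(a) list(m11 = a$m11, m12 = a$m21, m21 = a$m12, m22 = a$m22)

jv_apply <- function(a, v) {
  list(a$m11 * v[[1L]] + a$m12 * v[[2L]],
       a$m21 * v[[1L]] + a$m22 * v[[2L]])
}

# Detected Jones vector for a single-pass sample operator S (component
# list): E = J_Q S^T S J_Q e_in.  Returns list(EH, EV).
jv_detect <- function(S) {
  JQ <- jones_qwp()
  e0 <- as.vector(JQ %*% jones_input_state())
  u <- jv_apply(S, list(e0[1L], e0[2L]))
  w <- jv_apply(jv_t(S), u)
  list(EH = JQ[1L, 1L] * w[[1L]] + JQ[1L, 2L] * w[[2L]],
       EV = JQ[2L, 1L] * w[[1L]] + JQ[2L, 2L] * w[[2L]])
}
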