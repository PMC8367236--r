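# Shared fixtures: small phantoms and hand-built pipeline objects.

# Quick phantom: small enough for unit tests, big enough that the
# default segmentation rules (100-px seeds, 5x5 kernels) are exercised.
small_phantom_spec <- function(...) {
  defaults <- list(nx = 96L, ny = 32L, nz = 220L,
                   z_ilm = 60L, z_ref = 130L,
                   rpe_offset_px = 50L,
                   lesions = list(list(center_mm = c(0, 0), radius_mm = 1.3,
                                       delta = 30, theta = 40)))
  override <- list(...)
  do.call(phantom_spec,
          c(override, defaults[!names(defaults) %in% names(override)]))
}

# Noise-free, speckle-free variant for exactness checks.
clean_phantom_spec <- function(...) {
  small_phantom_spec(speckle = FALSE, noise_sd = 0, ...)
}

# Build a polarization_volume by hand (unit-test plumbing).
fake_pol <- function(delta, theta, R = NULL,
                     pitch = c(x = 10, y = 10, z = 1.39)) {
  if (is.null(R)) R <- array(1, dim(delta))
  structure(list(R = R, delta = delta, theta = theta,
                 invalid = array(FALSE, dim(delta)), pitch = pitch),
            class = "polarization_volume")
}

# Build a variance_map by hand.
fake_vmap <- function(v, valid = NULL, kernel = c(5L, 5L)) {
  if (is.null(valid)) valid <- !is.na(v)
  structure(list(v = v, n = (valid) * 1L, valid = valid, kernel = kernel),
            class = "variance_map")
}

# Build an axis_map by hand from an axis matrix in radians.
fake_axis_map <- function(axis, valid = NULL,
                          pitch = c(x = 8000 / 1024, y = 6000 / 250)) {
  if (is.null(valid)) valid <- !is.na(axis)
  structure(list(resultant = exp(2i * axis), axis = axis,
                 n_valid = valid * 1L, valid = valid, pitch = pitch),
            class = "axis_map")
}

# Detected Jones vector of a single-pass operator chain (independent
# oracle route for small cases; mirrors the instrument model).
detect_from_stack <- function(...) {
  mats <- list(...)
  S <- diag(2) + 0i
  for (J in mats) S <- J %*% S
  JQ <- jones_qwp()
  E <- JQ %*% t(S) %*% S %*% JQ %*% c(0, 1)
  c(EH = E[1L], EV = E[2L])
}

expect_axis_equal <- function(a_deg, b_deg, tol = 1e-6) {
  d <- ((a_deg - b_deg + 90) %% 180) - 90
  expect_lt(max(abs(d)), tol)
}
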