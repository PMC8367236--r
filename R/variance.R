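# Circular variance of axis orientations (optic axis uniformity).
#
# Axis orientations are pi-periodic, so they are doubled before being
# treated as directions on the full circle.  The circular variance in a
# kernel is one minus the length of the mean resultant vector of the
# doubled-angle unit vectors: 0 when all axes agree, 1 when they point
# in opposing (doubled) directions.

# Shared core: doubled-angle circular variance over a sliding 2D
# kernel with valid-neighbor averaging and border cropping.
circular_variance_core <- function(theta, valid, kernel) {
  z <- exp(2i * theta)
  z[!valid | is.na(theta)] <- 0i
  n <- box_sum2d((valid & !is.na(theta)) * 1, kernel)
  zb <- box_sum2d(z, kernel)
  ok <- n > 0
  v <- ifelse(ok, 1 - Mod(zb) / n, NA_real_)
  v[ok & v < 0] <- 0
  list(v = v, n = n, valid = ok)
}

#' Circular-variance map of an axis-orientation en-face map
#'
#' For each pixel the doubled-angle circular variance of the axis
#' orientations in a surrounding kernel (default 5 x 5 pixels) is
#' assigned to the central pixel.  Invalid axis pixels are excluded
#' from the kernel average; kernels are cropped at the map borders.
#' Fibrotic tissue has a locally uniform optic axis and shows low
#' variance; polarization-maintaining or depolarizing tissue shows a
#' random axis pattern and variance near 1.
#'
#' @param x an `axis_map` from [depth_averaged_axis()], or a plain
#'   numeric matrix of axis orientations in radians.
#' @param kernel odd kernel size `c(kx, ky)`; default 5 x 5.
#' @param valid optional logical matrix when `x` is a plain matrix.
#' @return an object of class `variance_map`: list with matrix `v` in
#'   `[0, 1]` (`NA` where the kernel holds no valid pixel), `n`,
#'   logical `valid` and the `kernel`.
#' @export
circular_variance_map <- function(x, kernel = c(5L, 5L), valid = NULL) {
  kernel <- check_odd_kernel(kernel)
  if (inherits(x, "axis_map")) {
    theta <- x$axis
    valid <- x$valid
  } else {
    theta <- as.matrix(x)
    if (is.null(valid)) valid <- !is.na(theta)
  }
  out <- circular_variance_core(theta, valid, kernel)
  structure(list(v = out$v, n = out$n, valid = out$valid, kernel = kernel),
            class = "variance_map")
}

#' Axis-variance B-scan
#'
#' The same doubled-angle circular variance applied in the B-scan
#' (depth x transverse) plane, by default in a 41 x 41 pixel
#' neighborhood.  Severely fibrotic tissue shows column-like structures
#' of uniform axis in depth and hence low variance; non-birefringent
#' tissue stays near 1.
#'
#' @param theta_bscan numeric matrix `[nz, nx]` of compensated axis
#'   orientations in radians (e.g. `comp$theta[, , y]`).
#' @param kernel odd kernel size, default 41 x 41.
#' @param valid optional logical matrix of usable pixels.
#' @return a `variance_map` over the B-scan plane.
#' @export
variance_bscan <- function(theta_bscan, kernel = c(41L, 41L), valid = NULL) {
  kernel <- check_odd_kernel(kernel)
  theta_bscan <- as.matrix(theta_bscan)
  if (is.null(valid)) valid <- !is.na(theta_bscan)
  out <- circular_variance_core(theta_bscan, valid, kernel)
  structure(list(v = out$v, n = out$n, valid = out$valid, kernel = kernel),
            class = "variance_map")
}
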