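# Accuracy analysis of the single-step compensation approximation.

#' Axis-recovery error of single-step vs exact compensation
#'
#' A two-layer anterior stack (cornea + Henle's fiber layer) is not a
#' single linear retarder in single pass, so compensating it with one
#' effective linear retarder sampled at a reference surface leaves a
#' small residual error in the recovered axis orientation of a
#' posterior (fibrotic) retarder.  This function quantifies that error
#' by forward-modeling the full Jones chain for every combination of
#' relative axis orientations, running the package's own extraction and
#' compensation machinery on the resulting synthetic A-scans, and
#' comparing the recovered posterior axis with the ground truth.
#'
#' Each synthetic A-scan holds three noise-free voxels: one reflecting
#' at the ILM (cornea only traversed), one at the reference surface
#' below the HFL (cornea + HFL traversed) and one inside the posterior
#' retarder.  With `iterative = FALSE` the compensation uses the
#' reference surface only (single effective retarder); with
#' `iterative = TRUE` the two-step variant (cornea at the ILM, then HFL
#' at the reference surface) is used, which recovers the posterior axis
#' exactly.
#'
#' @param delta_cornea,delta_hfl double-pass retardations of the
#'   anterior layers in degrees (defaults: typical cornea 20, maximum
#'   HFL 14).
#' @param delta_post double-pass retardation of the posterior test
#'   retarder in degrees.  The axis error is independent of this value.
#' @param theta_hfl,theta_post sweep grids (degrees) for the HFL axis
#'   relative to the cornea (fixed at 0) and for the posterior axis.
#' @param theta_cornea cornea axis in degrees (default 0; only relative
#'   axes matter).
#' @param iterative logical; use the two-step compensation.
#' @return list with `errors` (matrix of signed axis errors in degrees,
#'   `theta_hfl` by `theta_post`), `max_error_deg`, and `n` (number of
#'   configurations evaluated).
#' @export
#' @examples
#' sw <- axis_error_sweep(theta_hfl = seq(-90, 88, by = 2),
#'                        theta_post = seq(-90, 80, by = 10))
#' sw$max_error_deg
axis_error_sweep <- function(delta_cornea = 20, delta_hfl = 14,
                             delta_post = 30,
                             theta_hfl = seq(-90, 89.75, by = 0.25),
                             theta_post = seq(-90, 85, by = 5),
                             theta_cornea = 0,
                             iterative = FALSE) {
  nx <- length(theta_hfl)
  ny <- length(theta_post)
  thH <- matrix(deg2rad(theta_hfl), nx, ny)
  thF <- matrix(deg2rad(theta_post), nx, ny, byrow = TRUE)
  dC <- deg2rad(delta_cornea)
  dH <- deg2rad(delta_hfl)
  dF <- deg2rad(delta_post)

  JC <- jv_const(jones_linear_retarder(delta_cornea, theta_cornea),
                 template = thH)
  JH <- jv_retarder(array(dH, dim(thH)), thH)
  JF <- jv_retarder(array(dF, dim(thF)), thF)
  S_ilm <- JC
  S_ref <- jv_mul(JH, JC)
  S_les <- jv_mul(JF, S_ref)

  EH <- array(0i, c(3L, nx, ny))
  EV <- array(0i, c(3L, nx, ny))
  for (i in seq_along(list(S_ilm, S_ref, S_les))) {
    E <- jv_detect(list(S_ilm, S_ref, S_les)[[i]])
    EH[i, , ] <- E$EH
    EV[i, , ] <- E$EV
  }
  tomo <- complex_tomogram(EH, EV)
  pol <- extract_polarization(tomo)
  ref_surface <- matrix(2, nx, ny)
  if (iterative) {
    comp <- compensate_iterative(pol, matrix(1, nx, ny), ref_surface,
                                 smooth = c(1L, 1L))
  } else {
    comp <- compensate(pol, sample_reference(pol, ref_surface,
                                             smooth = c(1L, 1L)))
  }
  errors <- rad2deg(axis_diff_rad(comp$theta[3L, , ], thF))
  list(errors = errors,
       max_error_deg = max(abs(errors)),
       n = nx * ny)
}

#' Added circular variance of the single-step approximation
#'
#' The single-step axis error varies only gradually with position along
#' a circle about the foveal center (where the HFL axis is the local
#' azimuth).  This function builds the analytic error field on an
#' en-face grid with the HFL axis radial about the map center, computes
#' the doubled-angle circular variance of the recovered axis of a
#' uniform posterior retarder inside a sliding kernel, and returns the
#' maximum over the pixels of a circle of given radius.  Since the true
#' axis is constant, any variance is added by the approximation alone.
#'
#' @param radius_mm radius of the evaluation circle about the map
#'   center (default 1.5 mm, the retardation peak of the phantom's HFL
#'   doughnut).
#' @param nx,ny,extent_mm en-face grid (defaults: 1024 x 250 over
#'   8 x 6 mm).
#' @param kernel variance kernel, default 5 x 5.
#' @inheritParams axis_error_sweep
#' @return list with `max_added_variance` and the full `variance` map.
#' @export
added_variance_on_circle <- function(delta_cornea = 20, delta_hfl = 14,
                                     delta_post = 30, theta_post = 25,
                                     radius_mm = 1.5,
                                     nx = 1024L, ny = 250L,
                                     extent_mm = c(8, 6),
                                     kernel = c(5L, 5L)) {
  kernel <- check_odd_kernel(kernel)
  px <- extent_mm[1L] / nx
  py <- extent_mm[2L] / ny
  xs <- (seq_len(nx) - (nx + 1) / 2) * px
  ys <- (seq_len(ny) - (ny + 1) / 2) * py
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  az <- wrap_axis(atan2(Y, X), degrees = FALSE)

  # recovered posterior axis for each pixel's HFL axis
  JC <- jv_const(jones_linear_retarder(delta_cornea, 0), template = az)
  JH <- jv_retarder(array(deg2rad(delta_hfl), dim(az)), az)
  JF <- jv_const(jones_linear_retarder(delta_post, theta_post), template = az)
  S_ref <- jv_mul(JH, JC)
  S_les <- jv_mul(JF, S_ref)
  extr <- function(E) {
    list(delta = atan2(Mod(E$EV), Mod(E$EH)),
         theta = wrap_axis((pi - (Arg(E$EV) - Arg(E$EH))) / 2, degrees = FALSE))
  }
  ref <- extr(jv_detect(S_ref))
  mes <- extr(jv_detect(S_les))
  Jj <- jv_retarder(mes$delta, mes$theta)
  Jc <- jv_retarder(-ref$delta, ref$theta)
  N <- jv_mul(Jc, jv_mul(jv_mul(Jj, Jj), Jc))
  JQ <- jones_qwp()
  e0 <- as.vector(JQ %*% jones_input_state())
  w <- jv_apply(N, list(e0[1L], e0[2L]))
  EHc <- JQ[1L, 1L] * w[[1L]] + JQ[1L, 2L] * w[[2L]]
  EVc <- JQ[2L, 1L] * w[[1L]] + JQ[2L, 2L] * w[[2L]]
  theta_rec <- wrap_axis((pi - (Arg(EVc) - Arg(EHc))) / 2, degrees = FALSE)

  z <- exp(2i * theta_rec)
  n <- box_sum2d(matrix(1, nx, ny), kernel)
  v <- 1 - Mod(box_sum2d(z, kernel) / n)
  r <- sqrt(X^2 + Y^2)
  ring <- abs(r - radius_mm) <= max(px, py)
  list(max_added_variance = max(v[ring]), variance = v)
}
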