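# Extraction of reflectivity, retardation, axis orientation and DOPU
# from the two detection channels.

#' Extract polarization parameters from a two-channel tomogram
#'
#' Per voxel, with channel amplitudes \eqn{A_H = |E_H|},
#' \eqn{A_V = |E_V|} and phase difference
#' \eqn{\Delta\Phi = \arg E_V - \arg E_H}:
#' \deqn{R \propto A_H^2 + A_V^2}
#' \deqn{\delta = \arctan(A_V / A_H) \in [0^\circ, 90^\circ]}
#' \deqn{\theta = (\pi - \Delta\Phi)/2, wrapped to [-90^\circ, +90^\circ)}
#'
#' `delta` is the measured (double-pass) retardation of the joint
#' effective linear retarder formed by everything the beam traversed
#' anterior to the voxel.  Axis orientations are relative: the
#' polarization-maintaining fiber optics add an unknown constant
#' offset, so only axis differences within a volume are meaningful.
#'
#' @param tomo a [complex_tomogram()].
#' @return an object of class `polarization_volume`: list with arrays
#'   `R` (arbitrary units), `delta` and `theta` (radians; see
#'   [wrap_axis()]), logical `invalid` (voxels with zero signal in both
#'   channels, where delta/theta are undefined) and the pixel `pitch`.
#' @export
extract_polarization <- function(tomo) {
  stopifnot(inherits(tomo, "complex_tomogram"))
  if (length(tomo$EH) == 0L) stop("tomogram channels are empty", call. = FALSE)
  AH <- Mod(tomo$EH)
  AV <- Mod(tomo$EV)
  R <- AH^2 + AV^2
  invalid <- R == 0
  delta <- atan2(AV, AH)
  dphi <- Arg(tomo$EV) - Arg(tomo$EH)
  theta <- wrap_axis((pi - dphi) / 2, degrees = FALSE)
  delta[invalid] <- NA_real_
  theta[invalid] <- NA_real_
  structure(list(R = R, delta = delta, theta = theta, invalid = invalid,
                 pitch = tomo$pitch),
            class = "polarization_volume")
}

#' @export
print.polarization_volume <- function(x, ...) {
  d <- dim(x$R)
  cat(sprintf("<polarization_volume> %d x %d x %d voxels (%.2f%% invalid)\n",
              d[1L], d[2L], d[3L], 100 * mean(x$invalid)))
  invisible(x)
}

# Stokes elements from a tomogram or an already extracted volume.
# Both parameterizations carry the same information:
#   I = AH^2 + AV^2,  Q = AH^2 - AV^2,
#   U = 2 AH AV cos(dPhi),  V = 2 AH AV sin(dPhi)
# with dPhi = pi - 2 theta when starting from (R, delta, theta).
stokes_elements <- function(x) {
  if (inherits(x, "complex_tomogram")) {
    AH <- Mod(x$EH)
    AV <- Mod(x$EV)
    dphi <- Arg(x$EV) - Arg(x$EH)
    list(I = AH^2 + AV^2, Q = AH^2 - AV^2,
         U = 2 * AH * AV * cos(dphi), V = 2 * AH * AV * sin(dphi))
  } else if (inherits(x, "polarization_volume")) {
    s2d <- sin(2 * x$delta)
    th2 <- 2 * x$theta
    U <- -x$R * s2d * cos(th2)
    V <- x$R * s2d * sin(th2)
    U[x$invalid] <- 0
    V[x$invalid] <- 0
    Q <- x$R * cos(2 * x$delta)
    Q[x$invalid] <- 0
    list(I = x$R, Q = Q, U = U, V = V)
  } else {
    stop("need a complex_tomogram or polarization_volume", call. = FALSE)
  }
}

#' Degree of polarization uniformity (DOPU)
#'
#' Per voxel the normalized Stokes elements Q/I, U/I, V/I are averaged
#' over a sliding kernel in the B-scan plane (axial x transverse) and
#' the DOPU is the norm of the averaged vector,
#' \eqn{\sqrt{\bar Q^2 + \bar U^2 + \bar V^2}}.  Depolarizing tissue
#' (the retinal pigment epithelium) scrambles the backscattered
#' polarization state from voxel to voxel, so its averaged vector is
#' short and DOPU drops well below 1.
#'
#' Zero-intensity voxels are excluded from the kernel averages; kernels
#' are cropped at the image borders.
#'
#' @param x a [complex_tomogram()] or a `polarization_volume`.
#' @param kernel kernel size `c(axial, transverse)` in pixels, both
#'   odd.  Default 5 x 5.
#' @return an object of class `dopu_volume`: list with array `dopu` in
#'   `[0, 1]`, logical `valid` (kernels containing at least one
#'   non-zero-intensity voxel) and the `kernel` used.
#' @export
compute_dopu <- function(x, kernel = c(5L, 5L)) {
  kernel <- check_odd_kernel(kernel)
  st <- stokes_elements(x)
  d <- dim(st$I)
  ok <- st$I > 0
  dopu <- array(NA_real_, d)
  valid <- array(FALSE, d)
  mat <- function(a, y) matrix(a[, , y], d[1L], d[2L])
  for (y in seq_len(d[3L])) {
    I <- mat(st$I, y)
    w <- mat(ok, y)
    qn <- ifelse(w, mat(st$Q, y) / I, 0)
    un <- ifelse(w, mat(st$U, y) / I, 0)
    vn <- ifelse(w, mat(st$V, y) / I, 0)
    n <- box_sum2d(w * 1, kernel)
    nz <- n > 0
    qb <- ifelse(nz, box_sum2d(qn, kernel) / n, NA_real_)
    ub <- ifelse(nz, box_sum2d(un, kernel) / n, NA_real_)
    vb <- ifelse(nz, box_sum2d(vn, kernel) / n, NA_real_)
    dopu[, , y] <- sqrt(qb^2 + ub^2 + vb^2)
    valid[, , y] <- nz
  }
  # numerical round-off can push the norm marginally above 1
  over <- which(!is.na(dopu) & dopu > 1)
  dopu[over] <- 1
  structure(list(dopu = dopu, valid = valid, kernel = kernel),
            class = "dopu_volume")
}
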