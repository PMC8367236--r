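# Numerical compensation of anterior-segment birefringence.
#
# Everything the beam traverses anterior to a voxel acts, in double
# pass, like a single effective linear retarder (Jones reversibility:
# any stack of linear retarders with negligible diattenuation is
# equivalent in round trip to one linear retarder).  Sampling the
# extracted (delta, theta) at a reference surface located just below
# the last anterior birefringent layer therefore yields the parameters
# (delta_R, theta_R) of that effective retarder, and a compensator with
# theta_comp = theta_R, delta_comp = -delta_R, inserted on both sides
# of the per-voxel joint retarder, removes the anterior influence:
#
#   E_comp = J_Q . J_comp . J_joint^2 . J_comp . J_Q . (0,1)^T
#
# with J_joint = J(delta, theta) rebuilt from the voxel's extracted
# values.  Re-extracting (A_H, A_V, dPhi) from E_comp gives the
# compensated retardation and axis orientation.

#' Sample the compensation reference at a segmented surface
#'
#' Reads the extracted retardation and axis orientation at a per-A-scan
#' reference depth (typically the IS/OS junction or the top of the
#' lesion for full anterior compensation, or the ILM for cornea-only
#' compensation).  The resulting maps are median-filtered transversally
#' to suppress speckle: retardation by an ordinary median, axis
#' orientation component-wise on the doubled-angle unit vectors so the
#' \eqn{\pm 90^\circ} wrap is respected.
#'
#' @param pol a `polarization_volume` from [extract_polarization()].
#' @param surface numeric matrix `[nx, ny]` of 1-based depth indices;
#'   `NA` marks columns without a surface.
#' @param smooth median filter size `c(kx, ky)`; `c(1, 1)` disables
#'   smoothing.  Default 5 x 5.
#' @param min_intensity reflectivity floor below which the surface
#'   voxel is considered too dark to trust (default 0 = no floor).
#' @return an object of class `reference_map`: list with matrices
#'   `delta`, `theta` (radians) and logical `valid`.
#' @export
sample_reference <- function(pol, surface, smooth = c(5L, 5L), min_intensity = 0) {
  stopifnot(inherits(pol, "polarization_volume"))
  d <- dim(pol$R)
  surface <- as.matrix(surface)
  if (!identical(dim(surface), d[2:3])) {
    stop("surface must be an nx-by-ny matrix matching the tomogram grid",
         call. = FALSE)
  }
  z <- round(surface)
  inrange <- !is.na(z) & z >= 1 & z <= d[1L]
  zz <- ifelse(inrange, z, 1L)
  xs <- as.vector(row(surface))
  ys <- as.vector(col(surface))
  lin <- as.vector(zz) + (xs - 1L) * d[1L] + (ys - 1L) * d[1L] * d[2L]
  valid <- inrange &
    matrix(!pol$invalid[lin], d[2L], d[3L]) &
    matrix(pol$R[lin] >= min_intensity, d[2L], d[3L])
  delta <- matrix(pol$delta[lin], d[2L], d[3L])
  theta <- matrix(pol$theta[lin], d[2L], d[3L])
  delta[!valid] <- NA_real_
  theta[!valid] <- NA_real_
  smooth <- check_odd_kernel(smooth)
  if (any(smooth > 1L)) {
    delta <- median_filter2d(delta, smooth)
    zr <- median_filter2d(cos(2 * theta), smooth)
    zi <- median_filter2d(sin(2 * theta), smooth)
    theta <- wrap_axis(atan2(zi, zr) / 2, degrees = FALSE)
    valid <- valid & !is.na(delta) & !is.na(theta)
    delta[!valid] <- NA_real_
    theta[!valid] <- NA_real_
  }
  structure(list(delta = delta, theta = theta, valid = valid),
            class = "reference_map")
}

#' Compensate anterior birefringence with a single effective retarder
#'
#' Applies the single-step numerical compensation: per voxel the joint
#' effective linear retarder is rebuilt from the extracted
#' `(delta, theta)`, the per-column compensator
#' `J(-delta_R, theta_R)` is inserted adjacent to the quarter-wave
#' plate on both sides, and compensated retardation and axis
#' orientation are re-extracted from the resulting Jones vector.
#' Reflectivity is unchanged (the chain is unitary).
#'
#' Columns whose reference is invalid are passed through unchanged and
#' flagged in `column_valid`.
#'
#' @param x a [complex_tomogram()] or a `polarization_volume`.
#' @param reference a `reference_map` from [sample_reference()].
#' @return an object of class `compensation_result`: list with
#'   `delta` and `theta` (compensated volumes, radians), `R`,
#'   `invalid` (per-voxel), `reference`, `column_valid` (`[nx, ny]`),
#'   and `pitch`.
#' @export
compensate <- function(x, reference) {
  pol <- if (inherits(x, "complex_tomogram")) extract_polarization(x) else x
  stopifnot(inherits(pol, "polarization_volume"),
            inherits(reference, "reference_map"))
  d <- dim(pol$R)
  if (!identical(dim(reference$valid), d[2:3])) {
    stop("reference map does not match the tomogram transverse grid",
         call. = FALSE)
  }
  JQ <- jones_qwp()
  e0 <- as.vector(JQ %*% jones_input_state())
  delta_out <- pol$delta
  theta_out <- pol$theta
  for (y in seq_len(d[3L])) {
    cols <- which(reference$valid[, y])
    if (length(cols) == 0L) next
    dl <- matrix(pol$delta[, cols, y], d[1L])
    th <- matrix(pol$theta[, cols, y], d[1L])
    bad <- is.na(dl)
    dl[bad] <- 0
    th[bad] <- 0
    Jj <- jv_retarder(dl, th)
    # broadcast the per-column compensator along depth
    dr <- matrix(rep(-reference$delta[cols, y], each = d[1L]), d[1L])
    tr <- matrix(rep(reference$theta[cols, y], each = d[1L]), d[1L])
    Jc <- jv_retarder(dr, tr)
    M <- jv_mul(Jj, Jj)            # double-pass joint retarder
    N <- jv_mul(Jc, jv_mul(M, Jc)) # compensator on both sides
    w <- jv_apply(N, list(e0[1L], e0[2L]))
    EH <- JQ[1L, 1L] * w[[1L]] + JQ[1L, 2L] * w[[2L]]
    EV <- JQ[2L, 1L] * w[[1L]] + JQ[2L, 2L] * w[[2L]]
    dnew <- atan2(Mod(EV), Mod(EH))
    tnew <- wrap_axis((pi - (Arg(EV) - Arg(EH))) / 2, degrees = FALSE)
    dnew[bad] <- NA_real_
    tnew[bad] <- NA_real_
    delta_out[, cols, y] <- dnew
    theta_out[, cols, y] <- tnew
  }
  structure(list(delta = delta_out, theta = theta_out, R = pol$R,
                 invalid = pol$invalid, reference = reference,
                 column_valid = reference$valid, pitch = pol$pitch),
            class = "compensation_result")
}

#' @export
print.compensation_result <- function(x, ...) {
  d <- dim(x$R)
  cat(sprintf(
    "<compensation_result> %d x %d x %d voxels, %.1f%% columns compensated\n",
    d[1L], d[2L], d[3L], 100 * mean(x$column_valid)))
  invisible(x)
}

# Reinterpret a compensation result as a polarization volume so it can
# be fed back through sample_reference()/compensate().
as_polarization_volume <- function(comp) {
  stopifnot(inherits(comp, "compensation_result"))
  structure(list(R = comp$R, delta = comp$delta, theta = comp$theta,
                 invalid = comp$invalid, pitch = comp$pitch),
            class = "polarization_volume")
}

#' Two-step iterative compensation
#'
#' Validation variant of [compensate()]: step 1 compensates the cornea
#' using the ILM as reference surface; step 2 re-samples the reference
#' at the IS/OS (or lesion) surface of the step-1 output and
#' compensates the remaining retinal birefringence (RNFL + HFL).  For a
#' cornea-only anterior segment the result is identical to the
#' single-step compensation; for layered anterior stacks it removes the
#' small axis-orientation error of the single-step approximation.
#'
#' @param x a [complex_tomogram()] or a `polarization_volume`.
#' @param ilm_surface,reference_surface numeric matrices `[nx, ny]` of
#'   1-based depth indices; the ILM must be anterior to (or at) the
#'   reference surface wherever both are defined.
#' @param smooth median filter passed to [sample_reference()].
#' @param min_intensity reflectivity floor passed to [sample_reference()].
#' @return a `compensation_result` (reference = step-2 reference).
#' @export
compensate_iterative <- function(x, ilm_surface, reference_surface,
                                 smooth = c(5L, 5L), min_intensity = 0) {
  pol <- if (inherits(x, "complex_tomogram")) extract_polarization(x) else x
  both <- !is.na(ilm_surface) & !is.na(reference_surface)
  if (any(ilm_surface[both] > reference_surface[both])) {
    stop("surfaces crossing: ILM must be anterior to the reference surface",
         call. = FALSE)
  }
  ref1 <- sample_reference(pol, ilm_surface, smooth = smooth,
                           min_intensity = min_intensity)
  step1 <- compensate(pol, ref1)
  pol1 <- as_polarization_volume(step1)
  ref2 <- sample_reference(pol1, reference_surface, smooth = smooth,
                           min_intensity = min_intensity)
  out <- compensate(pol1, ref2)
  out$column_valid <- ref1$valid & ref2$valid
  out
}
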