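# Masked depth-averaged axis-orientation en-face maps.

#' Estimate the intensity noise floor
#'
#' Mean reflectivity of a signal-free margin: by convention the top
#' rows of every B-scan, which image vitreous in retinal OCT.  If the
#' margin is misconfigured to contain tissue the estimate is inflated;
#' this is documented behavior, not detected.
#'
#' @param R reflectivity volume `[nz, nx, ny]` (or a
#'   `polarization_volume`).
#' @param margin number of top rows to use (default 20).
#' @return scalar noise level (same units as `R`).
#' @export
estimate_noise_floor <- function(R, margin = 20L) {
  if (inherits(R, "polarization_volume")) R <- R$R
  margin <- as.integer(margin)
  if (margin < 1L || margin > dim(R)[1L]) {
    stop("noise margin must select a non-empty region within the volume",
         call. = FALSE)
  }
  mean(R[seq_len(margin), , ])
}

#' Depth-averaged axis-orientation map
#'
#' For every A-scan the compensated axis orientations between the
#' reference surface and the lower integration boundary are averaged in
#' complex space on doubled angles: the resultant is the mean of
#' \eqn{\exp(i 2\theta)} over the included voxels and the map axis is
#' half its argument.  Doubling respects the \eqn{\pi}-periodicity of
#' axis orientations; the average is unweighted.
#'
#' Excluded from the average are voxels of depolarizing tissue
#' (DOPU < `dopu_threshold`, default 0.8, i.e. the RPE) and voxels too
#' dark for reliable polarization data (intensity below
#' `intensity_factor` times the noise floor).  Columns flagged invalid
#' by the compensation or the surfaces, and columns with no included
#' voxel, are flagged and excluded from segmentation.
#'
#' @param comp a `compensation_result` (or `polarization_volume`).
#' @param surfaces a [surface_set()].
#' @param dopu a `dopu_volume` from [compute_dopu()], or `NULL` to skip
#'   the DOPU mask.
#' @param noise_floor scalar intensity noise level; estimated from the
#'   top margin when `NULL`.
#' @param dopu_threshold DOPU exclusion threshold (default 0.8).
#' @param intensity_factor noise-floor multiple below which voxels are
#'   excluded (default 2).
#' @return an object of class `axis_map`: list with matrices
#'   `resultant` (complex, `|resultant| <= 1`), `axis` (radians,
#'   `arg(resultant)/2`), `n_valid` (contributing voxels) and logical
#'   `valid`, plus the pixel `pitch`.
#' @export
depth_averaged_axis <- function(comp, surfaces, dopu = NULL,
                                noise_floor = NULL,
                                dopu_threshold = 0.8,
                                intensity_factor = 2) {
  stopifnot(inherits(surfaces, "surface_set"))
  col_ok <- if (inherits(comp, "compensation_result")) comp$column_valid else
    matrix(TRUE, dim(comp$R)[2L], dim(comp$R)[3L])
  d <- dim(comp$R)
  if (!identical(dim(surfaces$reference), d[2:3])) {
    stop("surfaces do not match the volume grid", call. = FALSE)
  }
  if (!is.null(dopu)) {
    stopifnot(inherits(dopu, "dopu_volume"))
    if (!identical(dim(dopu$dopu), d)) {
      stop("DOPU volume does not match the compensated volume", call. = FALSE)
    }
  }
  if (is.null(noise_floor)) noise_floor <- estimate_noise_floor(comp$R)

  zseq <- seq_len(d[1L])
  res <- matrix(0i, d[2L], d[3L])
  nval <- matrix(0L, d[2L], d[3L])
  for (y in seq_len(d[3L])) {
    zref <- surfaces$reference[, y]
    zlow <- surfaces$lower[, y]
    ok_col <- surfaces$valid[, y] & col_ok[, y] & !is.na(zref) & !is.na(zlow)
    zref[!ok_col] <- Inf
    zlow[!ok_col] <- -Inf
    inband <- outer(zseq, zref, ">=") & outer(zseq, zlow, "<=")
    incl <- inband & !matrix(comp$invalid[, , y], d[1L], d[2L]) &
      (matrix(comp$R[, , y], d[1L], d[2L]) >= intensity_factor * noise_floor)
    if (!is.null(dopu)) {
      dv <- matrix(dopu$dopu[, , y], d[1L], d[2L])
      incl <- incl & matrix(dopu$valid[, , y], d[1L], d[2L]) &
        !is.na(dv) & dv >= dopu_threshold
    }
    th <- matrix(comp$theta[, , y], d[1L], d[2L])
    z2 <- exp(2i * th)
    z2[!incl | is.na(th)] <- 0i
    incl <- incl & !is.na(th)
    res[, y] <- colSums(z2)
    nval[, y] <- colSums(incl)
  }
  valid <- nval > 0L
  resultant <- ifelse(valid, res / nval, NA_complex_)
  axis <- ifelse(valid, wrap_axis(Arg(resultant) / 2, degrees = FALSE),
                 NA_real_)
  structure(list(resultant = resultant, axis = axis, n_valid = nval,
                 valid = valid, pitch = comp$pitch[c("x", "y")]),
            class = "axis_map")
}

#' @export
print.axis_map <- function(x, ...) {
  cat(sprintf("<axis_map> %d x %d pixels, %.1f%% valid, median n=%d\n",
              nrow(x$axis), ncol(x$axis), 100 * mean(x$valid),
              as.integer(stats::median(x$n_valid[x$valid]))))
  invisible(x)
}
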