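# Layered digital eye phantom.
#
# The phantom forward-models the full detection chain: the vertically
# polarized input beam is converted to circular polarization by the
# quarter-wave plate, traverses the cornea (global linear retarder),
# the RNFL (axis radial about an optic-nerve-head center, retardation
# growing toward it), Henle's fiber layer (doughnut-shaped retardation
# with radial axis about the foveal center), optionally a birefringent
# fibrotic lesion patch with locally uniform axis, is reflected with a
# layer-dependent amplitude, and returns through the same stack and the
# quarter-wave plate (Jones reversibility: the return operator is the
# transpose of the forward stack).  A depolarizing RPE band applies an
# independent random linear retarder per voxel.  Fully developed
# speckle multiplies both channels by a shared circular complex
# Gaussian factor; additive circular complex Gaussian noise is
# independent per channel.
#
# Retardation bookkeeping: all retardation values in the spec are the
# measured (double-pass) values that the extraction equations report,
# which equal the retardation parameter of the per-pass Jones matrix.

#' Specify a digital eye phantom
#'
#' @param nx,ny,nz volume size (A-scans per B-scan, B-scans, depth
#'   pixels).  The desk-scale default 256 x 64 x 512 is scaled from the
#'   clinical 1024 x 250 grid.
#' @param extent_mm transverse extent `c(x, y)` in millimeters on the
#'   retina (default 8 x 6).
#' @param pitch_z_um axial pixel pitch in micrometers (default 1.39).
#' @param cornea `c(delta, theta)` in degrees: corneal double-pass
#'   retardation (typical 20) and axis.
#' @param rnfl list `(max_delta, center_mm, decay_mm)`: peak RNFL
#'   double-pass retardation (degrees), optic-nerve-head center in mm
#'   from the map center, exponential decay length.  The RNFL axis is
#'   the azimuth about the ONH center.
#' @param hfl list `(peak_delta, radius_mm)`: Henle-layer doughnut with
#'   peak double-pass retardation (degrees; maximum 14 in the eye) at
#'   `radius_mm` from the foveal (map) center and radial axis.
#' @param lesions list of lesion patches, each a list
#'   `(center_mm, radius_mm, delta, theta)`: disc center relative to
#'   the map center, radius, cumulative double-pass retardation at full
#'   depth traversal and uniform axis (degrees).  `list()` for no
#'   lesion.
#' @param z_ilm,z_ref depth indices (pixels) of the ILM and of the
#'   reference surface (IS/OS or lesion top) before tilt.
#' @param tilt_px surface tilt `c(x, y)`: linear depth ramp amplitude
#'   across the map, in pixels.
#' @param rnfl_thickness_px,hfl_thickness_px,lesion_thickness_px slab
#'   thicknesses over which the layer retardations accrue linearly.
#' @param rpe_offset_px,rpe_thickness_px depolarizing RPE band position
#'   below the reference surface and thickness.
#' @param reflectivity named amplitudes (arbitrary units) of the tissue
#'   zones: `vitreous`, `retina`, `reference` (bright band at the
#'   reference surface), `outer` (polarization-maintaining tissue
#'   below), `lesion`, `rpe`, `choroid`.
#' @param speckle logical; multiply by fully developed speckle.
#' @param noise_sd standard deviation of the additive complex Gaussian
#'   channel noise per quadrature (the intensity noise floor is
#'   `4 * noise_sd^2`).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(nx = 256L, ny = 64L, nz = 512L,
                         extent_mm = c(8, 6), pitch_z_um = 1.39,
                         cornea = c(delta = 20, theta = 30),
                         rnfl = list(max_delta = 6, center_mm = c(4.2, 0),
                                     decay_mm = 2),
                         hfl = list(peak_delta = 14, radius_mm = 1.5),
                         lesions = list(list(center_mm = c(0, 0),
                                             radius_mm = 1.1,
                                             delta = 30, theta = 40)),
                         z_ilm = 120L, z_ref = 260L, tilt_px = c(4, 2),
                         rnfl_thickness_px = 30L, hfl_thickness_px = 40L,
                         lesion_thickness_px = 40L,
                         rpe_offset_px = 50L, rpe_thickness_px = 12L,
                         reflectivity = c(vitreous = 0, retina = 0.18,
                                          reference = 1, outer = 0.12,
                                          lesion = 0.5, rpe = 0.8,
                                          choroid = 0.1),
                         speckle = TRUE, noise_sd = 0.003) {
  spec <- list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
               extent_mm = extent_mm, pitch_z_um = pitch_z_um,
               cornea = cornea, rnfl = rnfl, hfl = hfl, lesions = lesions,
               z_ilm = z_ilm, z_ref = z_ref, tilt_px = tilt_px,
               rnfl_thickness_px = rnfl_thickness_px,
               hfl_thickness_px = hfl_thickness_px,
               lesion_thickness_px = lesion_thickness_px,
               rpe_offset_px = rpe_offset_px,
               rpe_thickness_px = rpe_thickness_px,
               reflectivity = reflectivity,
               speckle = isTRUE(speckle), noise_sd = noise_sd)
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  bad <- function(field, why) {
    stop(sprintf("invalid phantom spec: field '%s' %s", field, why),
         call. = FALSE)
  }
  if (s$nx < 8L || s$ny < 4L || s$nz < 16L) bad("nx/ny/nz", "too small")
  if (s$cornea[["delta"]] < 0) bad("cornea", "has negative retardation")
  if (s$rnfl$max_delta < 0) bad("rnfl", "has negative retardation")
  if (s$hfl$peak_delta < 0) bad("hfl", "has negative retardation")
  if (s$noise_sd < 0) bad("noise_sd", "is negative")
  if (s$z_ilm >= s$z_ref) bad("z_ilm", "must be anterior to z_ref")
  if (s$z_ref + s$lesion_thickness_px + s$rpe_offset_px > s$nz) {
    bad("z_ref", "leaves no room for the posterior layers")
  }
  pitch <- c(s$extent_mm[1L] / s$nx, s$extent_mm[2L] / s$ny)
  for (i in seq_along(s$lesions)) {
    p <- s$lesions[[i]]
    if (p$delta < 0) bad(sprintf("lesions[[%d]]", i), "has negative retardation")
    if (any(abs(p$center_mm) + p$radius_mm >
              s$extent_mm / 2 + pmax(pitch, 0))) {
      bad(sprintf("lesions[[%d]]", i), "extends beyond the map bounds")
    }
  }
  invisible(s)
}

# mm coordinates of the en-face grid, origin at the map center
enface_coords_mm <- function(spec) {
  px <- spec$extent_mm[1L] / spec$nx
  py <- spec$extent_mm[2L] / spec$ny
  list(X = matrix((seq_len(spec$nx) - (spec$nx + 1) / 2) * px,
                  spec$nx, spec$ny),
       Y = matrix((seq_len(spec$ny) - (spec$ny + 1) / 2) * py,
                  spec$nx, spec$ny, byrow = TRUE),
       pitch = c(x = px * 1000, y = py * 1000, z = spec$pitch_z_um))
}

# Deterministic ground-truth fields implied by a phantom spec.
phantom_truth <- function(spec) {
  co <- enface_coords_mm(spec)
  X <- co$X
  Y <- co$Y
  # surfaces: linear tilt across the map
  ramp <- (X / spec$extent_mm[1L]) * spec$tilt_px[1L] +
    (Y / spec$extent_mm[2L]) * spec$tilt_px[2L]
  ilm <- round(spec$z_ilm + ramp)
  ref <- round(spec$z_ref + ramp)
  # RNFL: azimuth about the ONH center, retardation decaying away from it
  dxo <- X - spec$rnfl$center_mm[1L]
  dyo <- Y - spec$rnfl$center_mm[2L]
  rnfl_theta <- wrap_axis(atan2(dyo, dxo), degrees = FALSE)
  rnfl_delta <- deg2rad(spec$rnfl$max_delta) *
    exp(-sqrt(dxo^2 + dyo^2) / spec$rnfl$decay_mm)
  # HFL: doughnut about the foveal (map) center with radial axis
  r <- sqrt(X^2 + Y^2)
  rr <- r / spec$hfl$radius_mm
  hfl_theta <- wrap_axis(atan2(Y, X), degrees = FALSE)
  hfl_delta <- deg2rad(spec$hfl$peak_delta) * rr * exp((1 - rr^2) / 2)
  # lesion patches
  lesion_mask <- matrix(FALSE, spec$nx, spec$ny)
  lesion_delta <- matrix(0, spec$nx, spec$ny)
  lesion_theta <- matrix(0, spec$nx, spec$ny)
  for (p in spec$lesions) {
    inp <- (X - p$center_mm[1L])^2 + (Y - p$center_mm[2L])^2 <= p$radius_mm^2
    lesion_mask <- lesion_mask | inp
    lesion_delta[inp] <- deg2rad(p$delta)
    lesion_theta[inp] <- deg2rad(p$theta)
  }
  list(ilm = ilm, reference = ref,
       rpe_top = ref + spec$rpe_offset_px,
       rnfl = list(delta = rnfl_delta, theta = rnfl_theta),
       hfl = list(delta = hfl_delta, theta = hfl_theta),
       lesion_mask = lesion_mask,
       lesion = list(delta = lesion_delta, theta = lesion_theta),
       cornea = spec$cornea,
       pitch = co$pitch)
}

#' Generate a phantom tomogram with ground truth
#'
#' Runs the layered forward model of the phantom specification and
#' returns the two-channel complex tomogram together with the exact
#' ground truth (surfaces, lesion mask, per-layer retardation/axis
#' fields).  The result is bit-identical for identical seeds; the
#' ground truth does not depend on the seed at all.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer random seed for speckle, channel noise and the
#'   RPE depolarization.
#' @return list with elements `tomogram` (a [complex_tomogram()]) and
#'   `truth` (list: `ilm`, `reference`, `lesion_mask`, layer fields,
#'   `pitch`).
#' @export
generate_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  truth <- phantom_truth(spec)
  nz <- spec$nz
  nx <- spec$nx
  ny <- spec$ny
  zseq <- seq_len(nz)
  refl <- spec$reflectivity
  ref_band <- 3L
  rpe_top_off <- spec$rpe_offset_px
  rpe_bot_off <- spec$rpe_offset_px + spec$rpe_thickness_px
  EH <- array(0i, c(nz, nx, ny))
  EV <- array(0i, c(nz, nx, ny))
  frac <- function(zmat, top, thick) {
    f <- (zmat - matrix(top, nz, nx, byrow = TRUE)) / thick
    f[f < 0] <- 0
    f[f > 1] <- 1
    f
  }
  JC <- jones_linear_retarder(spec$cornea[["delta"]], spec$cornea[["theta"]])
  for (y in seq_len(ny)) {
    ilm <- truth$ilm[, y]
    ref <- truth$reference[, y]
    Z <- matrix(zseq, nz, nx)
    f_rnfl <- frac(Z, ilm, spec$rnfl_thickness_px)
    f_hfl <- frac(Z, ref - spec$hfl_thickness_px, spec$hfl_thickness_px)
    lesion_cols <- truth$lesion_mask[, y]
    f_fib <- frac(Z, ref, spec$lesion_thickness_px)
    f_fib <- sweep(f_fib, 2L, lesion_cols * 1, "*")

    bcast <- function(v) matrix(v, nz, nx, byrow = TRUE)
    S <- jv_const(JC, template = Z)
    S <- jv_mul(jv_retarder(f_rnfl * bcast(truth$rnfl$delta[, y]),
                            bcast(truth$rnfl$theta[, y])), S)
    S <- jv_mul(jv_retarder(f_hfl * bcast(truth$hfl$delta[, y]),
                            bcast(truth$hfl$theta[, y])), S)
    S <- jv_mul(jv_retarder(f_fib * bcast(truth$lesion$delta[, y]),
                            bcast(truth$lesion$theta[, y])), S)
    # depolarizing RPE: independent random linear retarder per voxel
    in_rpe <- Z >= bcast(ref + rpe_top_off) & Z < bcast(ref + rpe_bot_off)
    n_rpe <- sum(in_rpe)
    if (n_rpe > 0L) {
      rd <- matrix(0, nz, nx)
      rt <- matrix(0, nz, nx)
      rd[in_rpe] <- stats::runif(n_rpe, 0, pi)
      rt[in_rpe] <- stats::runif(n_rpe, -pi / 2, pi / 2)
      S <- jv_mul(jv_retarder(rd, rt), S)
    }
    E <- jv_detect(S)
    # layer-dependent reflection amplitude
    amp <- matrix(refl[["vitreous"]], nz, nx)
    amp[Z >= bcast(ilm)] <- refl[["retina"]]
    below_band <- Z >= bcast(ref + ref_band)
    amp[below_band] <- refl[["outer"]]
    in_lesion <- below_band & f_fib > 0 &
      Z < bcast(ref + spec$lesion_thickness_px)
    amp[in_lesion] <- refl[["lesion"]]
    amp[Z >= bcast(ref) & !below_band] <- refl[["reference"]]
    amp[in_rpe] <- refl[["rpe"]]
    amp[Z >= bcast(ref + rpe_bot_off)] <- refl[["choroid"]]
    g <- if (spec$speckle) {
      (stats::rnorm(nz * nx) + 1i * stats::rnorm(nz * nx)) / sqrt(2)
    } else 1
    scale <- 0.5 * amp * g
    EH[, , y] <- E$EH * scale +
      spec$noise_sd * (stats::rnorm(nz * nx) + 1i * stats::rnorm(nz * nx))
    EV[, , y] <- E$EV * scale +
      spec$noise_sd * (stats::rnorm(nz * nx) + 1i * stats::rnorm(nz * nx))
  }
  tomo <- complex_tomogram(EH, EV, pitch = truth$pitch)
  list(tomogram = tomo, truth = truth, spec = spec)
}
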