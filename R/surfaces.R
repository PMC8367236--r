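# Retinal surface handling: phantom-adequate surface finding, the lower
# integration boundary, and CSV import/export of externally segmented
# surfaces.

#' Surface set for compensation and depth integration
#'
#' @param ilm,reference,lower numeric matrices `[nx, ny]` of 1-based
#'   depth indices (`NA` = undefined); the ILM (retinal top), the
#'   compensation reference (IS/OS junction or lesion top) and the
#'   lower integration boundary.
#' @param valid logical matrix; default: all three surfaces defined.
#' @return an object of class `surface_set`.
#' @export
surface_set <- function(ilm, reference, lower, valid = NULL) {
  stopifnot(identical(dim(ilm), dim(reference)),
            identical(dim(ilm), dim(lower)))
  if (is.null(valid)) valid <- !is.na(ilm) & !is.na(reference) & !is.na(lower)
  ok <- valid & !is.na(ilm) & !is.na(reference) & !is.na(lower)
  if (any(ilm[ok] > reference[ok]) || any(reference[ok] > lower[ok])) {
    stop("surface ordering violated: need ilm <= reference <= lower",
         call. = FALSE)
  }
  structure(list(ilm = ilm, reference = reference, lower = lower,
                 valid = valid),
            class = "surface_set")
}

# Transverse box smoothing of a volume (speckle suppression before
# edge detection; retinal surfaces are transversally smooth).
smooth_transverse <- function(R, k = c(5L, 3L)) {
  if (all(k <= 1L)) return(R)
  k <- check_odd_kernel(k)
  d <- dim(R)
  ones <- matrix(1, d[2L], d[3L])
  n <- box_sum2d(ones, k)
  out <- R
  for (z in seq_len(d[1L])) {
    out[z, , ] <- box_sum2d(matrix(R[z, , ], d[2L], d[3L]), k) / n
  }
  out
}

# Running-mean smoothing along depth, column-wise, window w (odd).
smooth_depth <- function(R, w = 5L) {
  if (w <= 1L) return(R)
  d <- dim(R)
  flat <- matrix(R, d[1L], prod(d[-1L]))
  kern <- rep(1 / w, w)
  # pad with edge replication so the window mean is defined everywhere
  h <- w %/% 2L
  padded <- rbind(flat[rep(1L, h), , drop = FALSE], flat,
                  flat[rep(d[1L], h), , drop = FALSE])
  sm <- as.matrix(stats::filter(padded, kern, sides = 2L))
  array(sm[(h + 1L):(h + d[1L]), , drop = FALSE], d)
}

#' Estimate the ILM surface from reflectivity
#'
#' Per A-scan, the first depth at which the depth-smoothed reflectivity
#' exceeds `factor` times the noise floor.  Adequate for phantom data;
#' clinical volumes should import externally segmented surfaces
#' ([read_surfaces()]).
#'
#' @param R reflectivity volume `[nz, nx, ny]` (or a
#'   `polarization_volume`).
#' @param noise noise floor (see [estimate_noise_floor()]); estimated
#'   from the top margin when `NULL`.
#' @param factor detection threshold in noise-floor multiples.
#' @param smooth_z depth smoothing window (pixels).
#' @param smooth_xy transverse smoothing kernel `c(x, y)` applied
#'   before edge detection (speckle suppression).
#' @return numeric matrix `[nx, ny]` of depth indices, `NA` where no
#'   crossing exists.
#' @export
find_ilm <- function(R, noise = NULL, factor = 4, smooth_z = 5L,
                     smooth_xy = c(5L, 3L)) {
  if (inherits(R, "polarization_volume")) R <- R$R
  if (is.null(noise)) noise <- estimate_noise_floor(R)
  sm <- smooth_depth(smooth_transverse(R, smooth_xy), smooth_z)
  d <- dim(sm)
  above <- matrix(sm, d[1L], d[2L] * d[3L]) > max(noise * factor, 0)
  # require persistence: the crossing must hold for `run` consecutive
  # depth pixels, so isolated speckle/noise spikes cannot fake an ILM
  run <- 3L
  hold <- above
  for (k in seq_len(run - 1L)) {
    hold <- hold & rbind(above[-seq_len(k), , drop = FALSE],
                         matrix(FALSE, k, ncol(above)))
  }
  idx <- apply(hold, 2L, function(col) {
    w <- which(col)
    if (length(w)) w[1L] else NA_integer_
  })
  # depth smoothing advances the crossing by half the window
  matrix(pmin(as.numeric(idx) + smooth_z %/% 2L, d[1L]), d[2L], d[3L])
}

#' Find the compensation reference surface
#'
#' Per A-scan, the depth of the strongest rising edge of the smoothed
#' reflectivity below the ILM estimate -- on phantoms (and healthy
#' retinas) this is the top of the brightest posterior layer, the IS/OS
#' junction or the lesion surface.  Columns whose peak smoothed
#' reflectivity stays below `factor` times the noise floor are flagged
#' invalid (`NA`).
#'
#' Intended as phantom-adequate plumbing; clinical data should use
#' externally segmented surfaces instead.
#'
#' @inheritParams find_ilm
#' @param ilm optional ILM depth map `[nx, ny]`; the search starts
#'   `min_sep` pixels below it.  `NULL` searches the whole A-scan.
#' @param min_sep minimum separation from the ILM (pixels).
#' @inheritParams find_ilm
#' @return numeric matrix `[nx, ny]` of depth indices with `NA` for
#'   invalid columns.
#' @export
find_reference_surface <- function(R, ilm = NULL, noise = NULL, factor = 4,
                                   min_sep = 5L, smooth_z = 5L,
                                   smooth_xy = c(5L, 3L)) {
  if (inherits(R, "polarization_volume")) R <- R$R
  if (is.null(noise)) noise <- estimate_noise_floor(R)
  sm <- smooth_depth(smooth_transverse(R, smooth_xy), smooth_z)
  d <- dim(sm)
  grad <- sm
  grad[-1L, , ] <- sm[-1L, , ] - sm[-d[1L], , ]
  grad[1L, , ] <- 0
  flatg <- matrix(grad, d[1L], d[2L] * d[3L])
  flats <- matrix(sm, d[1L], d[2L] * d[3L])
  start <- if (is.null(ilm)) rep(1L, d[2L] * d[3L]) else
    pmax(1L, as.integer(round(as.vector(ilm))) + as.integer(min_sep))
  thr <- max(noise * factor, 0)
  idx <- vapply(seq_len(ncol(flatg)), function(j) {
    s0 <- start[j]
    if (is.na(s0) || s0 > d[1L]) return(NA_integer_)
    seg <- flatg[s0:d[1L], j]
    if (max(flats[s0:d[1L], j]) <= thr) return(NA_integer_)
    # first edge comparable to the strongest one: deeper bright layers
    # (e.g. the RPE) must not displace the reference surface
    strong <- which(seg >= 0.5 * max(seg))
    as.integer(s0 - 1L + strong[1L])
  }, integer(1L))
  # depth smoothing advances the rising edge by half the window
  matrix(pmin(as.numeric(idx) + smooth_z %/% 2L, d[1L]), d[2L], d[3L])
}

#' Build the lower integration boundary
#'
#' The depth-averaging of axis orientations must stop anterior to the
#' birefringent sclera.  The lower boundary is placed `base + amplitude`
#' pixels (default 100) beneath the reference surface at the map center
#' and decays to `base` pixels (default 50) at the image area edges,
#' with the transition shaped by a 2D Gaussian bump.
#'
#' @param reference reference surface depth map `[nx, ny]`.
#' @param nz volume depth (pixels); the boundary is clamped to it.
#' @param base edge offset in pixels.
#' @param amplitude additional central offset in pixels.
#' @param sigma Gaussian width in pixels; default one quarter of the
#'   shorter map dimension.
#' @param center bump center `c(x, y)` in pixels; default map center.
#' @return numeric matrix `[nx, ny]` of depth indices.
#' @export
build_lower_boundary <- function(reference, nz, base = 50, amplitude = 50,
                                 sigma = NULL, center = NULL) {
  nx <- nrow(reference)
  ny <- ncol(reference)
  if (is.null(sigma)) sigma <- min(nx, ny) / 4
  if (is.null(center)) center <- c((nx + 1) / 2, (ny + 1) / 2)
  dx2 <- (seq_len(nx) - center[1L])^2
  dy2 <- (seq_len(ny) - center[2L])^2
  bump <- exp(-outer(dx2, dy2, "+") / (2 * sigma^2))
  offset <- base + amplitude * bump
  pmin(reference + offset, nz)
}

#' Segment all surfaces of a volume
#'
#' Convenience wrapper: [find_ilm()], [find_reference_surface()] and
#' [build_lower_boundary()] combined into a [surface_set()].
#'
#' @inheritParams find_reference_surface
#' @param ... passed on to [build_lower_boundary()].
#' @return a `surface_set`.
#' @export
find_surfaces <- function(R, noise = NULL, factor = 4, min_sep = 5L,
                          smooth_z = 5L, smooth_xy = c(5L, 3L), ...) {
  if (inherits(R, "polarization_volume")) R <- R$R
  if (is.null(noise)) noise <- estimate_noise_floor(R)
  ilm <- find_ilm(R, noise = noise, factor = factor, smooth_z = smooth_z,
                  smooth_xy = smooth_xy)
  ref <- find_reference_surface(R, ilm = ilm, noise = noise, factor = factor,
                                min_sep = min_sep, smooth_z = smooth_z,
                                smooth_xy = smooth_xy)
  lower <- build_lower_boundary(ref, nz = dim(R)[1L], ...)
  valid <- !is.na(ilm) & !is.na(ref) & !is.na(lower)
  # guard against pathological columns where the edge sits above the ILM
  valid <- valid & (is.na(ilm) | is.na(ref) | ilm <= ref)
  surface_set(ilm, ref, lower, valid)
}

#' Write surfaces to CSV
#'
#' Long format with columns `x`, `y`, `z_index`, `label` (one row per
#' A-scan and surface; invalid columns are omitted).
#'
#' @param surfaces a `surface_set`.
#' @param path output CSV file.
#' @export
write_surfaces <- function(surfaces, path) {
  stopifnot(inherits(surfaces, "surface_set"))
  rows <- do.call(rbind, lapply(c("ilm", "reference", "lower"), function(lab) {
    m <- surfaces[[lab]]
    ok <- !is.na(m) & surfaces$valid
    data.frame(x = row(m)[ok], y = col(m)[ok], z_index = m[ok], label = lab)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read surfaces from CSV
#'
#' @param path CSV file as written by [write_surfaces()] (or produced
#'   externally with the same columns).
#' @param dims en-face grid size `c(nx, ny)`.
#' @return a `surface_set`.
#' @export
read_surfaces <- function(path, dims) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x", "y", "z_index", "label") %in% names(df)))
  grab <- function(lab) {
    m <- matrix(NA_real_, dims[1L], dims[2L])
    sub <- df[df$label == lab, ]
    m[cbind(sub$x, sub$y)] <- sub$z_index
    m
  }
  surface_set(grab("ilm"), grab("reference"), grab("lower"))
}
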