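# Two-channel complex tomogram container and its on-disk format.

#' Two-channel complex PS-OCT tomogram
#'
#' Container for the reconstructed complex tomograms of the horizontal
#' (H) and vertical (V) detection channels.  Arrays are indexed
#' `[z, x, y]`: depth (axial pixel, anterior-most first), A-scan
#' position within the B-scan, and B-scan index.
#'
#' @param EH,EV complex 3D arrays of identical dimension `c(nz, nx, ny)`.
#' @param pitch named numeric vector `c(x=, y=, z=)`, pixel pitches in
#'   micrometers per pixel.  The default corresponds to a 1024 x 250
#'   en-face grid covering 8 x 6 mm on the retina of a standard-length
#'   eye and an axial pitch of 1.39 um.
#' @return an object of class `complex_tomogram` with elements `EH`,
#'   `EV` and `pitch`.
#' @export
complex_tomogram <- function(EH, EV,
                             pitch = c(x = 8000 / 1024, y = 6000 / 250, z = 1.39)) {
  if (!is.complex(EH)) EH <- EH + 0i
  if (!is.complex(EV)) EV <- EV + 0i
  if (length(dim(EH)) != 3L || !identical(dim(EH), dim(EV))) {
    stop("EH and EV must be 3D arrays of identical dimension", call. = FALSE)
  }
  if (anyNA(EH) || anyNA(EV) ||
      any(!is.finite(Re(EH))) || any(!is.finite(Im(EH))) ||
      any(!is.finite(Re(EV))) || any(!is.finite(Im(EV)))) {
    stop("channel amplitudes must be finite", call. = FALSE)
  }
  stopifnot(all(c("x", "y", "z") %in% names(pitch)), all(pitch > 0))
  structure(list(EH = EH, EV = EV, pitch = pitch[c("x", "y", "z")]),
            class = "complex_tomogram")
}

#' @export
print.complex_tomogram <- function(x, ...) {
  d <- dim(x$EH)
  cat(sprintf(
    "<complex_tomogram> %d (z) x %d (x) x %d (y) voxels, pitch %.3g/%.3g/%.3g um (x/y/z)\n",
    d[1L], d[2L], d[3L], x$pitch["x"], x$pitch["y"], x$pitch["z"]))
  invisible(x)
}

tomogram_dim <- function(tomo) dim(tomo$EH)

#' Write a tomogram to a directory container
#'
#' The container holds one multi-page 32-bit float TIFF per channel
#' component (`EH_real`, `EH_imag`, `EV_real`, `EV_imag`; one page per
#' B-scan) plus a `meta.json` sidecar with the geometry, the pixel
#' pitches and the affine scaling applied to fit the TIFF value range.
#'
#' @param tomo a [complex_tomogram()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_tomogram <- function(tomo, path) {
  stopifnot(inherits(tomo, "complex_tomogram"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- tomogram_dim(tomo)
  comps <- list(EH_real = Re(tomo$EH), EH_imag = Im(tomo$EH),
                EV_real = Re(tomo$EV), EV_imag = Im(tomo$EV))
  scaling <- list()
  for (nm in names(comps)) {
    v <- comps[[nm]]
    lo <- min(v)
    hi <- max(v)
    span <- if (hi > lo) hi - lo else 1
    scaled <- (v - lo) / span
    pages <- lapply(seq_len(d[3L]), function(y) scaled[, , y])
    tiff::writeTIFF(pages, file.path(path, paste0(nm, ".tif")),
                    bits.per.sample = 32L)
    scaling[[nm]] <- list(offset = lo, scale = span)
  }
  meta <- list(format = "psoctfib-tomogram-v1",
               nz = d[1L], nx = d[2L], ny = d[3L],
               pitch_um = as.list(tomo$pitch),
               scaling = scaling)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a tomogram container written by [write_tomogram()]
#'
#' @param path container directory.
#' @return a [complex_tomogram()].
#' @export
read_tomogram <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  d <- c(meta$nz, meta$nx, meta$ny)
  comp <- function(nm) {
    pages <- tiff::readTIFF(file.path(path, paste0(nm, ".tif")), all = TRUE)
    sc <- meta$scaling[[nm]]
    arr <- array(0, d)
    for (y in seq_len(d[3L])) arr[, , y] <- pages[[y]] * sc$scale + sc$offset
    arr
  }
  complex_tomogram(
    EH = comp("EH_real") + 1i * comp("EH_imag"),
    EV = comp("EV_real") + 1i * comp("EV_imag"),
    pitch = c(x = meta$pitch_um$x, y = meta$pitch_um$y, z = meta$pitch_um$z))
}
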