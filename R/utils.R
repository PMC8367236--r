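# Internal numeric helpers shared across the pipeline.

deg2rad <- function(x) x * pi / 180

rad2deg <- function(x) x * 180 / pi

#' Wrap an axis orientation into \eqn{[-90^\circ, +90^\circ)}
#'
#' Optic axis orientations are \eqn{\pi}-periodic: an axis at
#' \eqn{\theta} and one at \eqn{\theta + 180^\circ} describe the same
#' physical orientation.  All axis values handled by the package are
#' reduced to the half-open interval \eqn{[-90, +90)} degrees
#' (\eqn{[-\pi/2, \pi/2)} radians).
#'
#' @param theta numeric vector of angles.
#' @param degrees logical; if `TRUE` (default) `theta` is in degrees,
#'   otherwise in radians.
#' @return wrapped angles on the same scale as the input.
#' @export
#' @examples
#' wrap_axis(c(-90, 90, 135, 270))
wrap_axis <- function(theta, degrees = TRUE) {
  half <- if (degrees) 90 else pi / 2
  ((theta + half) %% (2 * half)) - half
}

# pi-periodic signed difference a - b, radians, in [-pi/2, pi/2)
axis_diff_rad <- function(a, b) ((a - b + pi / 2) %% pi) - pi / 2

# Sliding-window box sum over a matrix, kernel cropped at the borders.
# k = c(rows, cols), both odd.  Works for numeric and complex input.
box_sum2d <- function(m, k) {
  nr <- nrow(m)
  nc <- ncol(m)
  hr <- k[1L] %/% 2L
  hc <- k[2L] %/% 2L
  S <- matrix(if (is.complex(m)) 0 + 0i else 0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- m
  S <- apply(S, 2L, cumsum)
  S <- t(apply(S, 1L, cumsum))
  r2 <- pmin(seq_len(nr) + hr, nr) + 1L
  r1 <- pmax(seq_len(nr) - hr, 1L)
  c2 <- pmin(seq_len(nc) + hc, nc) + 1L
  c1 <- pmax(seq_len(nc) - hc, 1L)
  S[r2, c2] - S[r1, c2] - S[r2, c1] + S[r1, c1]
}

# Median filter with NA-aware cropped kernels.  Cells whose whole
# neighborhood is NA stay NA.
median_filter2d <- function(m, k = c(5L, 5L)) {
  if (all(k == 1L)) return(m)
  nr <- nrow(m)
  nc <- ncol(m)
  offs <- expand.grid(dr = -(k[1L] %/% 2L):(k[1L] %/% 2L),
                      dc = -(k[2L] %/% 2L):(k[2L] %/% 2L))
  stack <- array(NA_real_, c(nr, nc, nrow(offs)))
  for (i in seq_len(nrow(offs))) {
    dr <- offs$dr[i]
    dc <- offs$dc[i]
    rsrc <- intersect(seq_len(nr) + dr, seq_len(nr))
    csrc <- intersect(seq_len(nc) + dc, seq_len(nc))
    stack[rsrc - dr, csrc - dc, i] <- m[rsrc, csrc]
  }
  out <- apply(stack, c(1L, 2L), stats::median, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

check_odd_kernel <- function(kernel) {
  if (length(kernel) == 1L) kernel <- rep(kernel, 2L)
  kernel <- as.integer(kernel)
  if (any(kernel < 1L) || any(kernel %% 2L == 0L)) {
    stop("kernel must be odd-sized in both dimensions", call. = FALSE)
  }
  kernel
}

stopifnot_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' must be finite numeric", name), call. = FALSE)
  }
  invisible(x)
}
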