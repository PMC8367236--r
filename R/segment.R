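# Seeded region-growing segmentation of fibrotic lesions on the
# circular-variance map, areal quantification, and the threshold-sweep
# likelihood map.

#' Segmentation parameters
#'
#' @param th1 seed variance threshold; connected regions with variance
#'   strictly below `th1` become seeds (default 0.21).
#' @param th2 growth threshold; pixels adjacent to the growing region
#'   with variance strictly below `th2` are added (default 0.36).
#' @param min_seed_px seed regions must be strictly larger than this
#'   many pixels (default 100).
#' @param dopu_threshold DOPU exclusion threshold used upstream
#'   (default 0.8).
#' @param intensity_factor intensity exclusion in noise-floor
#'   multiples used upstream (default 2).
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(th1 = 0.21, th2 = 0.36, min_seed_px = 100L,
                                dopu_threshold = 0.8, intensity_factor = 2) {
  if (!(th1 >= 0 && th1 < th2 && th2 <= 1)) {
    stop("need 0 <= th1 < th2 <= 1", call. = FALSE)
  }
  if (min_seed_px < 1L) stop("min_seed_px must be >= 1", call. = FALSE)
  structure(list(th1 = th1, th2 = th2, min_seed_px = as.integer(min_seed_px),
                 dopu_threshold = dopu_threshold,
                 intensity_factor = intensity_factor),
            class = "segmentation_params")
}

# 8-connected component labeling of a logical matrix via the pixel
# adjacency graph.  Returns an integer matrix (0 = background).
label_components <- function(mask) {
  nx <- nrow(mask)
  ny <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nx, ny)
  if (length(idx) == 0L) return(lab)
  pos <- seq_along(idx)
  map <- integer(nx * ny)
  map[idx] <- pos
  x <- ((idx - 1L) %% nx) + 1L
  y <- ((idx - 1L) %/% nx) + 1L
  edges <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    xn <- x + off[1L]
    yn <- y + off[2L]
    ok <- xn >= 1L & xn <= nx & yn >= 1L & yn <= ny
    nb <- (yn[ok] - 1L) * nx + xn[ok]
    hit <- map[nb] > 0L
    if (any(hit)) {
      edges <- rbind(edges, cbind(pos[ok][hit], map[nb][hit]))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  lab[idx] <- comp$membership
  lab
}

#' Detect segmentation seeds on a variance map
#'
#' Connected regions (8-connectivity) of pixels with variance strictly
#' below `th1`, strictly larger than `min_seed_px` pixels, are kept as
#' seeds for region growing.  Invalid variance pixels never seed.
#'
#' @param vmap a `variance_map` from [circular_variance_map()].
#' @param params a [segmentation_params()].
#' @param roi optional logical matrix restricting the search.
#' @return logical seed mask `[nx, ny]`.
#' @export
detect_seeds <- function(vmap, params = segmentation_params(), roi = NULL) {
  stopifnot(inherits(vmap, "variance_map"))
  low <- vmap$valid & !is.na(vmap$v) & vmap$v < params$th1
  if (!is.null(roi)) low <- low & roi
  lab <- label_components(low)
  if (max(lab) == 0L) return(low & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes > params$min_seed_px)
  matrix(lab %in% keep, nrow(lab), ncol(lab))
}

#' Grow lesion regions from seeds
#'
#' Iteratively (to fixpoint) adds every pixel 8-adjacent to the current
#' region whose variance is strictly below `th2` (and inside the ROI
#' when one is given).  Equivalently: the union of the 8-connected
#' components of `{v < th2}` that contain a seed pixel.
#'
#' @param vmap a `variance_map`.
#' @param seeds logical seed mask from [detect_seeds()].
#' @param params a [segmentation_params()].
#' @param roi optional logical matrix; growth is confined to it.
#' @param pitch optional pixel pitch `c(x, y)` in micrometers used to
#'   attach the lesion area.
#' @return an object of class `lesion_mask`: list with logical `mask`,
#'   `roi`, `pixel_count` and (when `pitch` given) `area_mm2`.
#' @export
region_grow <- function(vmap, seeds, params = segmentation_params(),
                        roi = NULL, pitch = NULL) {
  stopifnot(inherits(vmap, "variance_map"))
  seeds <- as.matrix(seeds)
  grow <- vmap$valid & !is.na(vmap$v) & vmap$v < params$th2
  if (!is.null(roi)) {
    grow <- grow & roi
    seeds <- seeds & roi
  }
  mask <- seeds
  if (any(seeds)) {
    lab <- label_components(grow)
    keep <- unique(lab[seeds & lab > 0L])
    mask <- matrix(lab %in% keep, nrow(lab), ncol(lab)) | seeds
  }
  out <- structure(list(mask = mask, roi = roi,
                        pixel_count = sum(mask), area_mm2 = NA_real_),
                   class = "lesion_mask")
  if (!is.null(pitch)) out$area_mm2 <- lesion_area(out, pitch = pitch)
  out
}

#' Lesion area in square millimeters
#'
#' Counts the segmented pixels and converts with the en-face pixel
#' area.  At the standard geometry (1024 x 250 pixels over 8 x 6 mm,
#' standard eye length) one pixel corresponds to 187.5 um^2.
#'
#' @param mask a `lesion_mask` or a logical matrix.
#' @param pitch pixel pitch `c(x, y)` in micrometers per pixel; give
#'   either this or `extent_mm`.
#' @param extent_mm map extent `c(x, y)` in millimeters (with the grid
#'   size taken from `mask`).
#' @return area in mm^2.
#' @export
#' @examples
#' m <- matrix(FALSE, 1024, 250); m[1:10, 1:10] <- TRUE
#' lesion_area(m, extent_mm = c(8, 6))  # 100 px * 187.5 um^2
lesion_area <- function(mask, pitch = NULL, extent_mm = NULL) {
  m <- if (inherits(mask, "lesion_mask")) mask$mask else as.matrix(mask)
  if (is.null(pitch)) {
    if (is.null(extent_mm)) stop("give either pitch or extent_mm", call. = FALSE)
    if (any(extent_mm <= 0)) stop("zero-extent geometry", call. = FALSE)
    pitch <- c(extent_mm[1L] * 1000 / nrow(m), extent_mm[2L] * 1000 / ncol(m))
  }
  if (any(pitch <= 0)) stop("zero-extent geometry", call. = FALSE)
  sum(m) * pitch[1L] * pitch[2L] / 1e6
}

#' Segment fibrotic lesions on an axis map
#'
#' Convenience wrapper: variance map, seed detection and region
#' growing in one call.
#'
#' @param axis_map an `axis_map` from [depth_averaged_axis()].
#' @param params a [segmentation_params()].
#' @param kernel variance kernel, default 5 x 5.
#' @param roi optional logical ROI matrix.
#' @return a `lesion_mask` (with `area_mm2` from the axis map pitch).
#' @export
segment_fibrosis <- function(axis_map, params = segmentation_params(),
                             kernel = c(5L, 5L), roi = NULL) {
  vmap <- circular_variance_map(axis_map, kernel = kernel)
  seeds <- detect_seeds(vmap, params, roi = roi)
  region_grow(vmap, seeds, params, roi = roi, pitch = axis_map$pitch)
}

#' Threshold-sweep likelihood map
#'
#' The segmentation is run repeatedly with the seed threshold `th1`
#' swept over `th1_grid` (default 0, 0.05, ..., 0.85; 18 runs) and the
#' growth threshold locked to `th2 = th1 + gap`.  Per pixel the
#' likelihood is `1 - th2*`, where `th2*` is the smallest growth
#' threshold whose run segments that pixel; pixels never segmented get
#' 0.  Because the masks nest across the sweep, regions detected at
#' strict thresholds carry high likelihood.
#'
#' @param x an `axis_map` or a precomputed `variance_map`.
#' @param th1_grid seed thresholds to sweep.
#' @param gap offset between growth and seed threshold (default 0.15).
#' @param min_seed_px minimum seed size (strictly larger than).
#' @param kernel variance kernel when `x` is an axis map.
#' @param roi optional logical ROI matrix.
#' @return an object of class `likelihood_map`: list with matrix `lh`
#'   in `[0, 1]` and the sweep definition.
#' @export
likelihood_map <- function(x, th1_grid = seq(0, 0.85, by = 0.05), gap = 0.15,
                           min_seed_px = 100L, kernel = c(5L, 5L),
                           roi = NULL) {
  vmap <- if (inherits(x, "variance_map")) x else
    circular_variance_map(x, kernel = kernel)
  th1_grid <- round(sort(th1_grid), 12L)  # seq() round-off must not
                                          # leak into strict thresholds
  lh <- matrix(0, nrow(vmap$v), ncol(vmap$v))
  hit <- matrix(FALSE, nrow(vmap$v), ncol(vmap$v))
  for (th1 in th1_grid) {
    th2 <- round(th1 + gap, 12L)
    params <- segmentation_params(th1 = th1, th2 = th2,
                                  min_seed_px = min_seed_px)
    seeds <- detect_seeds(vmap, params, roi = roi)
    mask <- region_grow(vmap, seeds, params, roi = roi)$mask
    new <- mask & !hit
    lh[new] <- 1 - th2
    hit <- hit | mask
  }
  structure(list(lh = lh, th1_grid = th1_grid, gap = gap),
            class = "likelihood_map")
}

#' Summarize repeated area measurements
#'
#' Mean, population standard deviation and coefficient of variation of
#' repeated lesion-area measurements of the same eye.
#'
#' @param areas numeric vector of areas in mm^2.
#' @return list with `mean`, `sd` (population convention, divisor n)
#'   and `cv` (sd/mean).
#' @export
#' @examples
#' lesion_repeatability(c(7.94, 8.57, 7.05))
lesion_repeatability <- function(areas) {
  stopifnot(length(areas) >= 2L, all(is.finite(areas)))
  m <- mean(areas)
  s <- sqrt(mean((areas - m)^2))
  list(mean = m, sd = s, cv = s / m)
}

#' Per-lesion report table
#'
#' @param mask a `lesion_mask`.
#' @param pitch pixel pitch `c(x, y)` in micrometers.
#' @return data frame with one row per connected lesion: `lesion`,
#'   `pixels`, `area_mm2`.
#' @export
lesion_report <- function(mask, pitch) {
  stopifnot(inherits(mask, "lesion_mask"))
  lab <- label_components(mask$mask)
  n <- max(lab)
  if (n == 0L) {
    return(data.frame(lesion = integer(), pixels = integer(),
                      area_mm2 = numeric()))
  }
  px <- tabulate(lab[lab > 0L], nbins = n)
  data.frame(lesion = seq_len(n), pixels = px,
             area_mm2 = px * pitch[1L] * pitch[2L] / 1e6)
}

#' Rasterize a region-of-interest polygon
#'
#' Even-odd rule point-in-polygon test over the en-face grid.  The
#' polygon is given in map pixel coordinates (x along the first map
#' dimension).
#'
#' @param polygon two-column matrix (or data frame) of vertices.
#' @param nx,ny grid size.
#' @return logical matrix `[nx, ny]`.
#' @export
roi_mask <- function(polygon, nx, ny) {
  p <- as.matrix(polygon)
  stopifnot(ncol(p) == 2L, nrow(p) >= 3L)
  gx <- as.vector(row(matrix(0, nx, ny)))
  gy <- as.vector(col(matrix(0, nx, ny)))
  inside <- rep(FALSE, nx * ny)
  nv <- nrow(p)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- p[i, 1L]; yi <- p[i, 2L]
    xj <- p[j, 1L]; yj <- p[j, 2L]
    crosses <- ((yi > gy) != (yj > gy)) &
      (gx < (xj - xi) * (gy - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nx, ny)
}

#' Read/write ROI polygons as JSON
#'
#' @param path JSON file.
#' @param polygon two-column matrix of vertices.
#' @return `read_roi` returns the vertex matrix.
#' @export
write_roi <- function(polygon, path) {
  p <- as.matrix(polygon)
  jsonlite::write_json(list(x = p[, 1L], y = p[, 2L]), path, digits = NA)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cbind(x = obj$x, y = obj$y)
}
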