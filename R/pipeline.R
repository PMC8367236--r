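# End-to-end pipeline orchestration, configuration and reporting.

#' Pipeline configuration
#'
#' A fully concrete parameter set for [run_pipeline()].  The effective
#' configuration is serialized alongside the outputs for provenance and
#' hashed into every output file name, so reruns with an unchanged
#' configuration overwrite deterministically.
#'
#' @param input path to a tomogram container ([write_tomogram()]), or
#'   `NULL` to simulate a phantom.
#' @param phantom a [phantom_spec()] (used when `input` is `NULL`).
#' @param out_dir output directory.
#' @param surfaces optional path to an externally segmented surface CSV
#'   ([read_surfaces()]); `NULL` finds surfaces on the data.
#' @param roi optional path to an ROI polygon JSON ([read_roi()]).
#' @param params a [segmentation_params()].
#' @param dopu_kernel DOPU averaging kernel `c(axial, transverse)`.
#' @param variance_kernel en-face circular-variance kernel.
#' @param noise_margin top rows used for the noise floor.
#' @param iterative logical; use two-step compensation.
#' @param likelihood logical; also compute the threshold-sweep
#'   likelihood map.
#' @param seed integer seed (phantom simulation).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, phantom = phantom_spec(),
                            out_dir = tempfile("psoctfib_"),
                            surfaces = NULL, roi = NULL,
                            params = segmentation_params(),
                            dopu_kernel = c(5L, 5L),
                            variance_kernel = c(5L, 5L),
                            noise_margin = 20L,
                            iterative = FALSE,
                            likelihood = TRUE,
                            seed = 1L) {
  structure(list(input = input, phantom = phantom, out_dir = out_dir,
                 surfaces = surfaces, roi = roi, params = params,
                 dopu_kernel = check_odd_kernel(dopu_kernel),
                 variance_kernel = check_odd_kernel(variance_kernel),
                 noise_margin = as.integer(noise_margin),
                 iterative = isTRUE(iterative),
                 likelihood = isTRUE(likelihood),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_yaml <- function(config) {
  ser <- unclass(config)
  ser$phantom <- if (is.null(config$input)) unclass(config$phantom) else NULL
  ser$params <- unclass(config$params)
  yaml::as.yaml(ser, precision = 12L)
}

config_hash <- function(config) {
  # hash the analysis parameters only -- where the outputs land must
  # not change what they are called
  stripped <- config
  stripped$out_dir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(config_yaml(stripped), tmp)
  substr(unname(tools::md5sum(tmp)), 1L, 8L)
}

write_map_png <- function(m, path, lo = NULL, hi = NULL, bit16 = FALSE) {
  m[is.na(m)] <- if (is.null(lo)) 0 else lo
  if (is.null(lo)) lo <- min(m)
  if (is.null(hi)) hi <- max(m)
  span <- if (hi > lo) hi - lo else 1
  # transpose so x runs horizontally in the image
  img <- t((m - lo) / span)
  png::writePNG(img, path, dpi = NULL,
                asp = NULL)
  invisible(path)
}

#' Run the full fibrosis segmentation pipeline
#'
#' Orchestrates all stages: tomogram input (or phantom simulation),
#' polarization extraction, DOPU, surface segmentation (or import),
#' anterior-birefringence compensation, noise floor, depth-averaged
#' axis map, circular-variance map, seeded region growing, areal
#' quantification and (optionally) the likelihood map.  All stage
#' products are written to the output directory with the configuration
#' hash embedded in every file name, plus a `report.csv` with one row
#' per segmented lesion and a log of the effective parameters.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the stage products (`tomogram`,
#'   `pol`, `dopu`, `surfaces`, `comp`, `axis_map`, `vmap`, `mask`,
#'   `report`, `likelihood`, `truth` when simulated, and `files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  fname <- function(what, ext) {
    file.path(config$out_dir, sprintf("%s_%s.%s", what, hash, ext))
  }
  log_lines <- c(sprintf("psoctfib pipeline, config %s", hash))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  truth <- NULL
  tomo <- stage("input", {
    if (is.null(config$input)) {
      sim <- generate_phantom(config$phantom, seed = config$seed)
      truth <- sim$truth
      sim$tomogram
    } else {
      if (!dir.exists(config$input)) {
        stop(sprintf("input '%s' not found", config$input))
      }
      read_tomogram(config$input)
    }
  })
  d <- tomogram_dim(tomo)
  log_lines <- c(log_lines,
                 sprintf("volume: %d x %d x %d", d[1L], d[2L], d[3L]))

  pol <- stage("extract", extract_polarization(tomo))
  dop <- stage("dopu", compute_dopu(pol, kernel = config$dopu_kernel))
  noise <- stage("noise", estimate_noise_floor(pol, margin = config$noise_margin))
  log_lines <- c(log_lines, sprintf("noise floor: %.6g", noise))

  surfaces <- stage("surfaces", {
    if (is.null(config$surfaces)) {
      find_surfaces(pol, noise = noise)
    } else {
      read_surfaces(config$surfaces, dims = d[2:3])
    }
  })

  comp <- stage("compensate", {
    if (config$iterative) {
      compensate_iterative(pol, surfaces$ilm, surfaces$reference)
    } else {
      compensate(pol, sample_reference(pol, surfaces$reference))
    }
  })

  amap <- stage("enface", depth_averaged_axis(
    comp, surfaces, dopu = dop, noise_floor = noise,
    dopu_threshold = config$params$dopu_threshold,
    intensity_factor = config$params$intensity_factor))

  roi <- NULL
  if (!is.null(config$roi)) {
    roi <- stage("roi", roi_mask(read_roi(config$roi), d[2L], d[3L]))
  }

  vmap <- stage("variance", circular_variance_map(
    amap, kernel = config$variance_kernel))
  seeds <- stage("seeds", detect_seeds(vmap, config$params, roi = roi))
  mask <- stage("segment", region_grow(vmap, seeds, config$params,
                                       roi = roi, pitch = amap$pitch))
  report <- stage("report", lesion_report(mask, pitch = amap$pitch))
  log_lines <- c(log_lines,
                 sprintf("lesions: %d, total area %.4f mm^2",
                         nrow(report), sum(report$area_mm2)))

  lh <- NULL
  if (config$likelihood) {
    lh <- stage("likelihood", likelihood_map(vmap, roi = roi,
                                             min_seed_px = config$params$min_seed_px))
  }

  files <- c(config = fname("config", "yaml"),
             report = fname("report", "csv"),
             log = fname("pipeline", "log"),
             axis = fname("axis_map", "png"),
             variance = fname("variance_map", "png"),
             mask = fname("lesion_mask", "png"))
  writeLines(config_yaml(config), files[["config"]])
  utils::write.csv(report, files[["report"]], row.names = FALSE)
  write_map_png(rad2deg(amap$axis), files[["axis"]], lo = -90, hi = 90)
  write_map_png(vmap$v, files[["variance"]], lo = 0, hi = 1)
  write_map_png(mask$mask * 1, files[["mask"]], lo = 0, hi = 1)
  if (!is.null(lh)) {
    files <- c(files, likelihood = fname("likelihood_map", "png"))
    write_map_png(lh$lh, files[["likelihood"]], lo = 0, hi = 1)
  }
  writeLines(log_lines, files[["log"]])

  invisible(list(tomogram = tomo, pol = pol, dopu = dop, surfaces = surfaces,
                 comp = comp, axis_map = amap, vmap = vmap, seeds = seeds,
                 mask = mask, report = report, likelihood = lh,
                 truth = truth, noise_floor = noise, files = files,
                 hash = hash))
}
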