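test_that("sample_reference reads the surface voxel and flags bad columns", {
  delta <- array(0, c(5, 3, 2))
  theta <- array(0, c(5, 3, 2))
  delta[4, 1, 1] <- 20 * pi / 180
  theta[4, 1, 1] <- 30 * pi / 180
  R <- array(1, c(5, 3, 2))
  R[2, 2, 1] <- 0  # dead voxel at the surface of column (2, 1)
  pol <- fake_pol(delta, theta, R)
  pol$invalid[2, 2, 1] <- TRUE
  surface <- matrix(c(4, 2, 2, 2, 2, 99), 3, 2)  # column (3,2) out of range
  ref <- sample_reference(pol, surface, smooth = c(1, 1))
  expect_equal(ref$delta[1, 1] * 180 / pi, 20)
  expect_equal(ref$theta[1, 1] * 180 / pi, 30)
  expect_false(ref$valid[2, 1])   # invalid voxel -> flagged, no error
  expect_false(ref$valid[3, 2])   # out-of-range surface -> flagged
  expect_true(ref$valid[1, 1])
})

test_that("single anterior retarder is compensated exactly", {
  # cornea (double-pass 20 deg at 30 deg) over posterior (30 deg at 10 deg)
  JC <- jones_linear_retarder(20, 30)
  JF <- jones_linear_retarder(30, 10)
  Eref <- detect_from_stack(JC)
  Eles <- detect_from_stack(JC, JF)
  EH <- array(c(Eref["EH"], Eles["EH"]), c(2, 1, 1))
  EV <- array(c(Eref["EV"], Eles["EV"]), c(2, 1, 1))
  pol <- extract_polarization(complex_tomogram(EH, EV))
  ref <- sample_reference(pol, matrix(1, 1, 1), smooth = c(1, 1))
  expect_equal(ref$delta[1, 1] * 180 / pi, 20, tolerance = 1e-9)
  expect_axis_equal(ref$theta[1, 1] * 180 / pi, 30, tol = 1e-9)
  comp <- compensate(pol, ref)
  expect_equal(comp$delta[2, 1, 1] * 180 / pi, 30, tolerance = 1e-9)
  expect_axis_equal(comp$theta[2, 1, 1] * 180 / pi, 10, tol = 1e-9)
  # and the reference voxel itself is nulled
  expect_lt(abs(comp$delta[1, 1, 1]) * 180 / pi, 1e-9)
})

test_that("zero reference retardation leaves the volume unchanged", {
  set.seed(9)
  EH <- array(stats::rnorm(24) + 1i * stats::rnorm(24), c(4, 3, 2))
  EV <- array(stats::rnorm(24) + 1i * stats::rnorm(24), c(4, 3, 2))
  pol <- extract_polarization(complex_tomogram(EH, EV))
  ref <- structure(list(delta = matrix(0, 3, 2),
                        theta = matrix(0.7, 3, 2),
                        valid = matrix(TRUE, 3, 2)),
                   class = "reference_map")
  comp <- compensate(pol, ref)
  expect_equal(comp$delta, pol$delta, tolerance = 1e-9)
  maxd <- max(abs(psoctfib:::axis_diff_rad(comp$theta, pol$theta)))
  expect_lt(maxd, 1e-9)
})

test_that("invalid reference columns pass through untouched and flagged", {
  JC <- jones_linear_retarder(20, 30)
  E <- detect_from_stack(JC)
  EH <- array(E["EH"], c(2, 2, 1))
  EV <- array(E["EV"], c(2, 2, 1))
  pol <- extract_polarization(complex_tomogram(EH, EV))
  ref <- structure(list(delta = matrix(c(-20 * pi / 180, NA), 2, 1),
                        theta = matrix(c(30 * pi / 180, NA), 2, 1),
                        valid = matrix(c(TRUE, FALSE), 2, 1)),
                   class = "reference_map")
  comp <- compensate(pol, ref)
  expect_false(comp$column_valid[2, 1])
  expect_equal(comp$delta[, 2, 1], pol$delta[, 2, 1])
  expect_equal(comp$theta[, 2, 1], pol$theta[, 2, 1])
})

test_that("compensation nulls retardation at the reference surface on a
           noise-free phantom, and recompensation is stable", {
  sim <- generate_phantom(clean_phantom_spec(), seed = 1)
  pol <- extract_polarization(sim$tomogram)
  ref <- sample_reference(pol, sim$truth$reference, smooth = c(1, 1))
  comp <- compensate(pol, ref)
  d <- dim(pol$R)
  idx <- cbind(as.vector(sim$truth$reference),
               as.vector(row(sim$truth$reference)),
               as.vector(col(sim$truth$reference)))
  resid <- abs(comp$delta[idx]) * 180 / pi
  expect_lt(stats::median(resid, na.rm = TRUE), 1)
  # re-sampling the reference from the compensated output yields ~0
  # retardation, so a second compensation changes nothing material
  pol2 <- psoctfib:::as_polarization_volume(comp)
  ref2 <- sample_reference(pol2, sim$truth$reference, smooth = c(1, 1))
  expect_lt(stats::median(abs(ref2$delta), na.rm = TRUE) * 180 / pi, 1)
  comp2 <- compensate(pol2, ref2)
  resid2 <- abs(comp2$delta[idx]) * 180 / pi
  expect_lt(stats::median(resid2, na.rm = TRUE), 1)
})

test_that("shape mismatches error; crossing surfaces error", {
  pol <- fake_pol(array(0, c(3, 2, 2)), array(0, c(3, 2, 2)))
  ref <- structure(list(delta = matrix(0, 5, 5), theta = matrix(0, 5, 5),
                        valid = matrix(TRUE, 5, 5)),
                   class = "reference_map")
  expect_error(compensate(pol, ref), "grid")
  expect_error(
    compensate_iterative(pol, matrix(3, 2, 2), matrix(2, 2, 2)),
    "crossing")
})

test_that("iterative equals single-step for a cornea-only anterior segment", {
  spec <- clean_phantom_spec(rnfl = list(max_delta = 0, center_mm = c(4.2, 0),
                                         decay_mm = 2),
                             hfl = list(peak_delta = 0, radius_mm = 1.5))
  sim <- generate_phantom(spec, seed = 2)
  pol <- extract_polarization(sim$tomogram)
  single <- compensate(pol, sample_reference(pol, sim$truth$reference,
                                             smooth = c(1, 1)))
  iter <- compensate_iterative(pol, sim$truth$ilm, sim$truth$reference,
                               smooth = c(1, 1))
  # compare inside the lesion where retardation is well defined
  zmid <- sim$truth$reference + 20
  lm <- sim$truth$lesion_mask
  idx <- cbind(zmid[lm], row(lm)[lm], col(lm)[lm])
  dtheta <- psoctfib:::axis_diff_rad(single$theta[idx], iter$theta[idx])
  expect_lt(max(abs(dtheta)) * 180 / pi, 1e-6)
  expect_equal(single$delta[idx], iter$delta[idx], tolerance = 1e-6)
})

test_that("iterative compensation beats single-step under a layered
           anterior stack", {
  sw_single <- axis_error_sweep(theta_hfl = seq(-88, 88, by = 4),
                                theta_post = seq(-80, 80, by = 20))
  sw_iter <- axis_error_sweep(theta_hfl = seq(-88, 88, by = 4),
                              theta_post = seq(-80, 80, by = 20),
                              iterative = TRUE)
  expect_lt(sw_iter$max_error_deg, 1e-6)
  expect_true(all(abs(sw_iter$errors) <= abs(sw_single$errors) + 1e-9))
})
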