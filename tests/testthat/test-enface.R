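test_that("noise floor matches the analytic margin statistics", {
  set.seed(3)
  n <- 30 * 50 * 8
  sd <- 0.02
  EH <- array(sd * (stats::rnorm(n) + 1i * stats::rnorm(n)), c(30, 50, 8))
  EV <- array(sd * (stats::rnorm(n) + 1i * stats::rnorm(n)), c(30, 50, 8))
  pol <- extract_polarization(complex_tomogram(EH, EV))
  expect_equal(estimate_noise_floor(pol, margin = 20), 4 * sd^2,
               tolerance = 0.02)
  # zero-noise volume
  z <- complex_tomogram(array(0i, c(10, 4, 2)), array(0i, c(10, 4, 2)))
  expect_equal(estimate_noise_floor(extract_polarization(z), margin = 5), 0)
  expect_error(estimate_noise_floor(pol, margin = 0), "margin")
})

test_that("lower boundary is 100 px deep centrally, 50 px at the corners,
           and radially non-increasing", {
  ref <- matrix(200, 129, 65)
  low <- build_lower_boundary(ref, nz = 1000)
  expect_equal(low[65, 33], 200 + 100)
  expect_lt(abs(low[1, 1] - 250), 1)       # corner within 1 px of asymptote
  offs <- low - ref
  expect_true(all(offs >= 50 - 1e-9 & offs <= 100 + 1e-9))
  # non-increasing along a ray from the center
  ray <- offs[65:129, 33]
  expect_true(all(diff(ray) <= 1e-9))
  # clamped to the volume depth
  expect_true(all(build_lower_boundary(ref, nz = 220) <= 220))
})

test_that("reference surface finder recovers bright layers", {
  set.seed(8)
  nz <- 256; nx <- 40; ny <- 8
  mk <- function(depth_map) {
    EH <- array(0.001 * (stats::rnorm(nz * nx * ny) +
                           1i * stats::rnorm(nz * nx * ny)), c(nz, nx, ny))
    EV <- EH * 0
    for (y in seq_len(ny)) for (x in seq_len(nx)) {
      z <- depth_map[x, y]
      EH[z + 0:2, x, y] <- EH[z + 0:2, x, y] + 0.7
      EV[z + 0:2, x, y] <- EV[z + 0:2, x, y] + 0.7i
    }
    extract_polarization(complex_tomogram(EH, EV))
  }
  # flat bright layer at z = 200
  flat <- matrix(200L, nx, ny)
  got <- find_reference_surface(mk(flat))
  expect_lt(max(abs(got - 200), na.rm = TRUE), 2)
  # tilted bright plane recovered within 1 px RMS
  tilt <- matrix(100L + rep(round(seq(0, 39, length.out = nx))), nx, ny)
  got <- find_reference_surface(mk(tilt))
  expect_lt(sqrt(mean((got - tilt)^2, na.rm = TRUE)), 1.5)
  # pure-noise columns are invalid
  noise_only <- extract_polarization(complex_tomogram(
    array(0.001 * (stats::rnorm(nz * 4) + 1i * stats::rnorm(nz * 4)),
          c(nz, 4, 1)),
    array(0.001 * (stats::rnorm(nz * 4) + 1i * stats::rnorm(nz * 4)),
          c(nz, 4, 1))))
  expect_true(all(is.na(
    find_reference_surface(noise_only, noise = estimate_noise_floor(noise_only)))))
})

test_that("depth-averaged axis reproduces constant fields and flags
           fully masked columns", {
  nz <- 40; nx <- 6; ny <- 4
  theta <- array(25 * pi / 180, c(nz, nx, ny))
  pol <- fake_pol(array(0, c(nz, nx, ny)), theta)
  surf <- surface_set(matrix(5, nx, ny), matrix(10, nx, ny),
                      matrix(30, nx, ny))
  am <- depth_averaged_axis(pol, surf, noise_floor = 0)
  expect_equal(am$axis[am$valid] * 180 / pi, rep(25, sum(am$valid)))
  expect_equal(Mod(am$resultant[am$valid]), rep(1, sum(am$valid)))
  expect_equal(unique(am$n_valid[am$valid]), 21L)  # inclusive [10, 30]
  # all voxels below the intensity floor -> flagged column
  am2 <- depth_averaged_axis(pol, surf, noise_floor = 10)
  expect_true(all(!am2$valid))
})

test_that("resultant length of random axes follows sqrt(pi/(4n))", {
  set.seed(42)
  n <- 25; ncol_ <- 400
  theta <- array(stats::runif(n * ncol_, -pi / 2, pi / 2), c(n, ncol_, 1))
  pol <- fake_pol(array(0, dim(theta)), theta)
  surf <- surface_set(matrix(1, ncol_, 1), matrix(1, ncol_, 1),
                      matrix(n, ncol_, 1))
  am <- depth_averaged_axis(pol, surf, noise_floor = 0)
  got <- mean(Mod(am$resultant))
  # brute-force resampling oracle for E|mean of n uniform doubled angles|
  reps <- replicate(500, Mod(mean(exp(2i * stats::runif(n, -pi / 2, pi / 2)))))
  expect_lt(abs(got - mean(reps)), 4 * stats::sd(reps) / sqrt(ncol_))
  expect_equal(mean(reps), sqrt(pi / (4 * n)), tolerance = 0.05)
})

test_that("axis map is equivariant under a global axis offset and
           invariant under the 180-degree wrap", {
  set.seed(6)
  nz <- 30; nx <- 8; ny <- 5
  theta <- array(stats::runif(nz * nx * ny, -pi / 2, pi / 2), c(nz, nx, ny))
  pol <- fake_pol(array(0, dim(theta)), theta)
  surf <- surface_set(matrix(2, nx, ny), matrix(5, nx, ny),
                      matrix(25, nx, ny))
  base <- depth_averaged_axis(pol, surf, noise_floor = 0)
  off <- 0.3
  shifted <- depth_averaged_axis(
    fake_pol(array(0, dim(theta)),
             psoctfib:::wrap_axis(theta + off, degrees = FALSE)),
    surf, noise_floor = 0)
  expect_equal(Mod(shifted$resultant), Mod(base$resultant), tolerance = 1e-9)
  d <- psoctfib:::axis_diff_rad(shifted$axis, base$axis)
  expect_equal(max(abs(d - off)), 0, tolerance = 1e-9)
  wrapped <- depth_averaged_axis(
    fake_pol(array(0, dim(theta)),
             psoctfib:::wrap_axis(theta + pi, degrees = FALSE)),
    surf, noise_floor = 0)
  expect_equal(wrapped$axis, base$axis, tolerance = 1e-9)
})

test_that("DOPU masking of the depolarizing RPE raises the resultant", {
  sim <- generate_phantom(small_phantom_spec(), seed = 4)
  pol <- extract_polarization(sim$tomogram)
  noise <- estimate_noise_floor(pol)
  surf <- surface_set(sim$truth$ilm, sim$truth$reference,
                      build_lower_boundary(sim$truth$reference,
                                           nz = dim(pol$R)[1]))
  ref <- sample_reference(pol, sim$truth$reference, smooth = c(1, 1))
  comp <- compensate(pol, ref)
  dop <- compute_dopu(pol)
  masked <- depth_averaged_axis(comp, surf, dopu = dop, noise_floor = noise)
  unmasked <- depth_averaged_axis(comp, surf, dopu = NULL, noise_floor = noise)
  lm <- sim$truth$lesion_mask
  both <- masked$valid & unmasked$valid & lm
  expect_gt(mean(Mod(masked$resultant[both])),
            mean(Mod(unmasked$resultant[both])))
})

test_that("phantom RPE band depresses DOPU; tissue outside stays high", {
  sim <- generate_phantom(small_phantom_spec(), seed = 12)
  dop <- compute_dopu(extract_polarization(sim$tomogram))
  nx <- dim(dop$dopu)[2]; ny <- dim(dop$dopu)[3]
  inband <- c(); outband <- c()
  for (y in seq(1, ny, by = 4)) for (x in seq(1, nx, by = 8)) {
    zr <- sim$truth$reference[x, y]
    inband <- c(inband, dop$dopu[(zr + 52):(zr + 58), x, y])
    outband <- c(outband, dop$dopu[(zr + 10):(zr + 35), x, y])
  }
  expect_lt(mean(inband, na.rm = TRUE), 0.8)
  expect_gt(mean(outband, na.rm = TRUE), 0.95)
})
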