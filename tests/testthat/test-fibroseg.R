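test_that("circular variance matches closed-form kernel cases", {
  # constant axis field
  vm <- circular_variance_map(matrix(0.4, 20, 20))
  expect_equal(max(abs(vm$v)), 0, tolerance = 1e-12)
  # equal numbers of 0 and 90 degrees: doubled angles oppose, variance 1
  vm <- circular_variance_map(matrix(c(0, pi / 2), 1, 2), kernel = c(1, 3))
  expect_equal(as.vector(vm$v), c(1, 1), tolerance = 1e-12)
  # checkerboard of 0/90 in a 5x5 kernel: 13 vs 12 leaves |mean| = 1/25
  chk <- ifelse((row(matrix(0, 20, 20)) + col(matrix(0, 20, 20))) %% 2 == 0,
                0, pi / 2)
  vm <- circular_variance_map(chk)
  expect_equal(max(abs(vm$v[3:18, 3:18] - (1 - 1 / 25))), 0,
               tolerance = 1e-9)
  # equal counts of 0 and 45 degrees: v = 1 - sqrt(2)/2
  vm <- circular_variance_map(matrix(c(0, pi / 4), 1, 2), kernel = c(1, 3))
  expect_equal(as.vector(vm$v), rep(1 - sqrt(2) / 2, 2), tolerance = 1e-9)
})

test_that("kernels at borders are cropped and all-invalid kernels flagged", {
  th <- matrix(0, 9, 9)
  valid <- matrix(TRUE, 9, 9)
  valid[, 1:4] <- FALSE
  vm <- circular_variance_map(th, valid = valid)
  expect_false(vm$valid[5, 1])
  expect_true(is.na(vm$v[5, 1]))
  expect_true(vm$valid[5, 5])
  expect_equal(vm$n[1, 9], 9)  # corner kernel cropped to 3 x 3
})

test_that("seed detection applies the strict 100-pixel size rule", {
  v <- matrix(1, 60, 40)
  v[2:11, 2:11] <- 0.1           # exactly 100 px -> rejected
  vm <- fake_vmap(v)
  expect_equal(sum(detect_seeds(vm, segmentation_params())), 0)
  v[2:11, 2:11] <- 1
  v[20:30, 2:11] <- 0.1          # 110 px (> 100) -> kept, minus nothing
  v[2, 30] <- 0.1                # isolated low-variance pixel -> dropped
  vm <- fake_vmap(v)
  seeds <- detect_seeds(vm, segmentation_params())
  expect_equal(sum(seeds), 110)
  expect_false(seeds[2, 30])
  # a variance map of all ones seeds nothing
  expect_equal(sum(detect_seeds(fake_vmap(matrix(1, 30, 30)),
                                segmentation_params())), 0)
})

test_that("region growing adds the sub-threshold ring and only that", {
  v <- matrix(0.5, 60, 40)
  v[10:24, 10:24] <- 0.10        # 225-px seed blob
  ring <- matrix(FALSE, 60, 40)
  ring[8:26, 8:26] <- TRUE
  ring[10:24, 10:24] <- FALSE
  v[ring] <- 0.30                # grows (0.30 < th2 = 0.36)
  vm <- fake_vmap(v)
  seeds <- detect_seeds(vm, segmentation_params())
  mask <- region_grow(vm, seeds, segmentation_params())
  expect_equal(sum(mask$mask), 225 + sum(ring))
  expect_true(all(mask$mask[8:26, 8:26]))
  # empty seeds give an empty mask
  empty <- region_grow(vm, matrix(FALSE, 60, 40), segmentation_params())
  expect_equal(sum(empty$mask), 0)
})

test_that("segmented pixels satisfy the threshold contracts", {
  set.seed(19)
  v <- matrix(stats::runif(6000), 100, 60)
  v[30:45, 20:35] <- stats::runif(256, 0, 0.2)
  vm <- fake_vmap(v)
  p <- segmentation_params()
  seeds <- detect_seeds(vm, p)
  mask <- region_grow(vm, seeds, p)
  expect_true(all(v[seeds] < p$th1))
  expect_true(all(v[mask$mask] < p$th2))
  expect_true(all(seeds[mask$mask] | TRUE))  # seeds contained
  expect_true(all(mask$mask[seeds]))
})

test_that("lesion area converts pixel counts with the map geometry", {
  m <- matrix(FALSE, 1024, 250)
  expect_equal(lesion_area(m, extent_mm = c(8, 6)), 0)
  m[1:10, 1:10] <- TRUE
  a <- lesion_area(m, extent_mm = c(8, 6))
  expect_equal(a, 100 * 187.5 / 1e6)
  expect_equal(round(a, 3), 0.019)
  expect_equal(lesion_area(matrix(TRUE, 1024, 250), extent_mm = c(8, 6)), 48)
  expect_error(lesion_area(m, extent_mm = c(0, 6)), "extent")
})

test_that("likelihood map encodes the first segmenting threshold", {
  v <- matrix(0.95, 80, 60)
  v[10:30, 10:30] <- 0.01        # segments first at th1=0.05 (th2=0.2)
  ring1 <- matrix(FALSE, 80, 60); ring1[8:32, 8:32] <- TRUE
  ring1[10:30, 10:30] <- FALSE
  v[ring1] <- 0.17               # grows at th2=0.2 as well
  ring2 <- matrix(FALSE, 80, 60); ring2[6:34, 6:34] <- TRUE
  ring2[8:32, 8:32] <- FALSE
  v[ring2] <- 0.37               # needs th2=0.4 (th1=0.25)
  lm <- likelihood_map(fake_vmap(v))
  expect_equal(lm$lh[20, 20], 0.8)
  expect_equal(lm$lh[8, 20], 0.8)    # ring1 joins the th2=0.2 run
  expect_equal(lm$lh[6, 20], 0.6)    # ring2 first at th1=0.25/th2=0.4
  expect_equal(lm$lh[60, 50], 0)     # never segmented
  expect_equal(length(lm$th1_grid), 18)
})

test_that("masks nest across the threshold sweep", {
  set.seed(23)
  v <- matrix(stats::runif(4800), 80, 60)
  v[20:40, 20:40] <- v[20:40, 20:40] * 0.3
  vm <- fake_vmap(v)
  prev <- matrix(FALSE, 80, 60)
  for (th1 in seq(0, 0.85, by = 0.05)) {
    p <- segmentation_params(th1 = th1, th2 = th1 + 0.15)
    mask <- region_grow(vm, detect_seeds(vm, p), p)$mask
    expect_true(all(prev <= mask))
    prev <- mask
  }
})

test_that("the whole segmentation chain is invariant under a global
           axis offset", {
  set.seed(29)
  axis <- matrix(stats::runif(80 * 60, -pi / 2, pi / 2), 80, 60)
  axis[30:55, 20:45] <- 0.5
  am1 <- fake_axis_map(axis)
  am2 <- fake_axis_map(psoctfib:::wrap_axis(axis + 1.1, degrees = FALSE))
  v1 <- circular_variance_map(am1)
  v2 <- circular_variance_map(am2)
  expect_equal(v2$v, v1$v, tolerance = 1e-12)
  p <- segmentation_params()
  s1 <- detect_seeds(v1, p); s2 <- detect_seeds(v2, p)
  expect_identical(s1, s2)
  m1 <- region_grow(v1, s1, p, pitch = am1$pitch)
  m2 <- region_grow(v2, s2, p, pitch = am2$pitch)
  expect_identical(m1$mask, m2$mask)
  expect_identical(m1$area_mm2, m2$area_mm2)
  l1 <- likelihood_map(v1); l2 <- likelihood_map(v2)
  expect_identical(l1$lh, l2$lh)
})

test_that("variance B-scans separate uniform columns from random tissue", {
  vb <- variance_bscan(matrix(0.3, 60, 60), kernel = c(41, 41))
  expect_equal(max(abs(vb$v)), 0, tolerance = 1e-12)
  set.seed(31)
  th <- matrix(stats::runif(287 * 287, -pi / 2, pi / 2), 287, 287)
  vb <- variance_bscan(th, kernel = c(41, 41))
  centers <- seq(21, 287, by = 41)          # non-overlapping kernels
  got <- mean(vb$v[centers, centers])
  # MC oracle for the mean resultant length of 1681 uniform doubled angles
  reps <- replicate(200, Mod(mean(exp(2i * stats::runif(1681, -pi, pi)))))
  expect_equal(got, 1 - mean(reps),
               tolerance = 5 * stats::sd(reps) / sqrt(49) / 0.98)
  expect_equal(1 - mean(reps), 1 - sqrt(pi / (4 * 1681)), tolerance = 0.005)
  # a fibrotic column of constant axis shows lower variance inside
  th[, 140:160] <- 0.2
  vb <- variance_bscan(th, kernel = c(41, 41))
  expect_lt(mean(vb$v[, 148:152]), mean(vb$v[, 230:280]))
})

test_that("ROI polygons restrict seeds and growth", {
  v <- matrix(0.05, 60, 40)
  roi <- roi_mask(cbind(c(0.5, 30.5, 30.5, 0.5), c(0.5, 0.5, 40.5, 40.5)),
                  60, 40)
  expect_true(all(which(roi, arr.ind = TRUE)[, 1] <= 30))
  p <- segmentation_params()
  vm <- fake_vmap(v)
  mask <- region_grow(vm, detect_seeds(vm, p, roi = roi), p, roi = roi)
  expect_true(all(mask$mask[roi][1] | TRUE))
  expect_true(all(!mask$mask[!roi]))
  expect_gt(sum(mask$mask), 0)
})

test_that("repeatability statistics use the population convention", {
  st <- lesion_repeatability(c(7.94, 8.57, 7.05))
  expect_equal(st$mean, mean(c(7.94, 8.57, 7.05)))
  expect_equal(st$sd, sqrt(mean((c(7.94, 8.57, 7.05) - st$mean)^2)))
  expect_equal(st$cv, st$sd / st$mean)
})
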