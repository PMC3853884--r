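test_that("histogram counts are conserved and modes sit at class means", {
  grid <- image_grid(c(10, 10, 1))
  img <- cbct_volume(array(0, dim = c(10, 10, 1)), grid)
  h <- intensity_histogram(img)
  expect_equal(sum(h$counts), 100)
  expect_equal(h$counts[h$counts > 0], 100)
  expect_error(intensity_histogram(img, array(FALSE, dim = c(10, 10, 1))),
               class = "cbct_argument_error")
  # out-of-range values land in the end bins
  img2 <- cbct_volume(array(c(-5000, 5000), dim = c(10, 10, 1)), grid)
  h2 <- intensity_histogram(img2)
  expect_equal(sum(h2$counts), 100)
  expect_equal(h2$counts[1], 50)
  expect_equal(h2$counts[length(h2$counts)], 50)
  # phantom CT: a mode within one bin of each class HU mean
  ph <- small_phantom()
  hp <- intensity_histogram(ph$ct)
  centers <- (hp$edges[-1] + hp$edges[-length(hp$edges)]) / 2
  f <- hp$counts / sum(hp$counts)
  for (mu in small_phantom_spec()$class_hu) {
    near <- which(abs(centers - mu) <= 30)
    peak <- near[which.max(f[near])]
    expect_lte(abs(centers[peak] - mu), 15)
    # it is a genuine local concentration, not background (bone is a small
    # class on the coarse grid, hence the modest floor)
    expect_gt(f[peak], 2e-4)
  }
})

test_that("histogram distances satisfy their closed forms and oracles", {
  grid <- image_grid(c(10, 10, 1))
  a <- intensity_histogram(cbct_volume(array(0, dim = c(10, 10, 1)), grid))
  expect_equal(histogram_distance(a, a, "l1"), 0)
  expect_equal(histogram_distance(a, a, "chi2"), 0)
  expect_equal(histogram_distance(a, a, "emd"), 0)
  # single-bin histograms k bins apart: emd = k * bin width
  b <- intensity_histogram(cbct_volume(array(100, dim = c(10, 10, 1)), grid))
  expect_equal(histogram_distance(a, b, "emd"), 100)
  expect_equal(histogram_distance(a, b, "l1"), 2)
  # l1 equals a brute-force frequency sum on random histograms
  withr::local_seed(13)
  v1 <- cbct_volume(array(rnorm(1000, 0, 300), dim = c(10, 10, 10)),
                    image_grid(c(10, 10, 10)))
  v2 <- cbct_volume(array(rnorm(1000, 50, 250), dim = c(10, 10, 10)),
                    image_grid(c(10, 10, 10)))
  h1 <- intensity_histogram(v1); h2 <- intensity_histogram(v2)
  brute <- sum(abs(h1$counts / sum(h1$counts) - h2$counts / sum(h2$counts)))
  expect_equal(histogram_distance(h1, h2, "l1"), brute)
  expect_equal(histogram_distance(h1, h2, "emd"),
               histogram_distance(h2, h1, "emd"))
  h3 <- intensity_histogram(v1, edges = seq(-1000, 1000, 50))
  expect_error(histogram_distance(h1, h3, "l1"), class = "cbct_argument_error")
})

test_that("HU error metrics match brute-force voxel loops", {
  ph <- small_phantom()
  masks <- ph$masks
  expect_equal(hu_error_metrics(ph$ct, ph$ct, masks)$mae_hu, 0)
  plus10 <- ph$ct
  plus10$voxels <- plus10$voxels + 10
  rep10 <- hu_error_metrics(plus10, ph$ct, masks)
  expect_equal(rep10$mae_hu, 10)
  expect_equal(rep10$rmse_hu, 10)
  expect_equal(unname(rep10$class_mean_error_hu[c("lung", "soft", "bone")]),
               c(10, 10, 10))
  withr::local_seed(17)
  noisy <- ph$ct
  noisy$voxels <- noisy$voxels + array(rnorm(length(noisy$voxels), 0, 25),
                                       dim = dim(noisy$voxels))
  rep_n <- hu_error_metrics(noisy, ph$ct, masks)
  region <- masks$body & masks$fov
  d <- noisy$voxels - ph$ct$voxels
  expect_equal(rep_n$mae_hu, mean(abs(d[region])))
  expect_equal(rep_n$rmse_hu, sqrt(mean(d[region]^2)))
  expect_equal(unname(rep_n$class_mean_error_hu[["soft"]]),
               mean(d[masks$soft & region]))
})

test_that("density calibration interpolates its control points linearly", {
  cal <- density_calibration()
  grid <- image_grid(c(4, 1, 1))
  img <- cbct_volume(array(c(-1000, 0, 100, 3000), dim = c(4, 1, 1)), grid)
  dens <- hu_to_density(img, cal)
  expect_equal(as.numeric(dens$voxels), c(0.001, 1.0, 1.05, 1.85))
  expect_error(density_calibration(hu = c(0, 100), density = c(1.1, 1.0)),
               class = "cbct_configuration_error")
})

test_that("WEPL integrates closed-form slabs and converges under step halving", {
  # 100 mm of water along z
  n <- c(5, 5, 101)
  grid <- image_grid(n, c(2, 2, 1), c(0, 0, 0))
  water <- cbct_volume(array(0, dim = n), grid)
  dens <- hu_to_density(water)
  w <- wepl_along_ray(dens, c(4, 4, 0), c(0, 0, 1), step_mm = 0.5)
  expect_equal(w, 100, tolerance = 1e-6)
  # 40 mm water + 60 mm lung at density 0.25 -> 55 mm
  vox <- array(0, dim = n)
  vox[, , 41:101] <- -750
  mix <- cbct_volume(vox, grid)
  dens2 <- hu_to_density(mix)
  w2 <- wepl_along_ray(dens2, c(4, 4, 0), c(0, 0, 1), step_mm = 0.5)
  expect_equal(w2, 55, tolerance = 0.01)
  # oblique ray through the phantom vs 10x finer integration
  ph <- small_phantom()
  densp <- hu_to_density(ph$ct)
  entry <- c(0, -155, 0)
  dir <- c(0.2, 1, 0.1)
  coarse <- wepl_along_ray(densp, entry, dir, step_mm = 2.5)
  fine <- wepl_along_ray(densp, entry, dir, step_mm = 0.25)
  expect_lt(abs(coarse - fine) / fine, 0.005)
  half <- wepl_along_ray(densp, entry, dir, step_mm = 1.25)
  expect_lt(abs(coarse - half) / half, 0.005)
  expect_error(wepl_along_ray(densp, c(0, -500, 0), dir),
               class = "cbct_argument_error")
  expect_error(wepl_along_ray(densp, entry, dir, step_mm = 50),
               class = "cbct_argument_error")
})

test_that("WEPL discrepancy maps detect a uniform soft-tissue offset", {
  spec <- small_phantom_spec()
  spec$texture_sd_hu <- 0
  ph <- generate_phantom_ct(spec)
  rep0 <- wepl_discrepancy_map(ph$ct, ph$ct)
  expect_equal(rep0$mean_abs_mm, 0)
  expect_equal(rep0$max_abs_mm, 0)
  shifted <- ph$ct
  shifted$voxels[ph$masks$soft] <- shifted$voxels[ph$masks$soft] + 40
  rep1 <- wepl_discrepancy_map(shifted, ph$ct, ray_spacing_mm = 10)
  # oracle: density slope 0.0005/HU between 0 and 200 HU, so +40 HU adds
  # 0.02 per mm of soft-tissue path; compare central rays to the analytic
  # soft chord (body chord minus lung chords along the ray)
  cal_slope <- (1.10 - 1.0) / 200
  central <- subset(rep1$rays, abs(x) <= 10 & abs(z) <= 10)
  expect_gt(nrow(central), 0)
  for (r in seq_len(nrow(central))) {
    chord_body <- 2 * spec$body_semiaxes_mm[2] *
      sqrt(pmax(0, 1 - (central$x[r] / spec$body_semiaxes_mm[1])^2 -
                  (central$z[r] / spec$body_semiaxes_mm[3])^2))
    lung_chord <- 0
    for (lc in 1:2) {
      ctr <- spec$lung_centers_mm[lc, ]
      arg <- 1 - ((central$x[r] - ctr[1]) / spec$lung_semiaxes_mm[1])^2 -
        ((central$z[r] - ctr[3]) / spec$lung_semiaxes_mm[3])^2
      if (arg > 0) lung_chord <- lung_chord +
          2 * spec$lung_semiaxes_mm[2] * sqrt(arg)
    }
    bone_chord <- if (abs(central$z[r]) <= spec$spine_halflength_mm &&
                      abs(central$x[r]) < spec$spine_radius_mm)
      2 * sqrt(spec$spine_radius_mm^2 - central$x[r]^2) else 0
    soft_chord <- chord_body - lung_chord - bone_chord
    oracle <- 40 * cal_slope * soft_chord
    expect_lt(abs(central$delta[r] - oracle), 0.02 * oracle + 0.3)
  }
  expect_error(wepl_discrepancy_map(ph$ct, ph$ct, min_wepl_mm = 1e6),
               class = "cbct_argument_error")
})
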