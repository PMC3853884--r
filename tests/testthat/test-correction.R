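test_that("HU <-> attenuation conversion is the documented linear map", {
  grid <- image_grid(c(4, 4, 4))
  img <- cbct_volume(array(c(-1000, 0, 500, -1500), dim = c(4, 4, 4)), grid)
  mu <- hu_to_mu(img)
  expect_equal(mu$voxels[1, 1, 1], 0)    # air
  expect_equal(mu$voxels[2, 1, 1], 1)    # water
  expect_equal(mu$voxels[3, 1, 1], 1.5)
  expect_equal(mu$voxels[4, 1, 1], 0)    # clamped below air
  back <- mu_to_hu(mu)
  expect_equal(back$voxels[2:3, 1, 1], c(0, 500))
})

test_that("ratio fields follow the clamped quotient contract", {
  grid <- image_grid(c(6, 6, 6))
  ones <- cbct_volume(array(1, dim = c(6, 6, 6)), grid, unit = "MU_RELATIVE")
  cb <- cbct_volume(array(0.8, dim = c(6, 6, 6)), grid, unit = "MU_RELATIVE")
  mask <- array(TRUE, dim = c(6, 6, 6))
  expect_equal(unique(as.numeric(
    compute_ratio_field(ones, ones, mask)$voxels)), 1)
  expect_equal(unique(as.numeric(
    compute_ratio_field(ones, cb, mask)$voxels)), 1.25)
  zero <- cbct_volume(array(0, dim = c(6, 6, 6)), grid, unit = "MU_RELATIVE")
  expect_equal(unique(as.numeric(
    compute_ratio_field(ones, zero, mask)$voxels)), 5)  # ceiling clamp
  expect_warning(
    r <- compute_ratio_field(ones, cb, array(FALSE, dim = c(6, 6, 6))),
    "empty")
  expect_true(all(is.na(r$voxels)))
})

test_that("mask-normalized smoothing preserves constants and hits the mean in the wide limit", {
  grid <- image_grid(c(16, 16, 16), c(1, 1, 1))
  mask <- array(FALSE, dim = c(16, 16, 16))
  mask[4:13, 4:13, 4:13] <- TRUE
  ratio <- array(NA_real_, dim = c(16, 16, 16))
  ratio[mask] <- 1.25
  rv <- cbct_volume(ratio, grid, unit = "RATIO")
  sm <- smooth_ratio_field(rv, mask, filter_spec(width_mm = 8))
  expect_lt(max(abs(sm$voxels[mask] - 1.25)), 1e-12)
  # very wide kernel: output approaches the mean of the defined ratios
  withr::local_seed(2)
  ratio2 <- array(NA_real_, dim = c(16, 16, 16))
  ratio2[mask] <- runif(sum(mask), 0.9, 1.1)
  rv2 <- cbct_volume(ratio2, grid, unit = "RATIO")
  sm2 <- smooth_ratio_field(rv2, mask, filter_spec(width_mm = 20 * 16))
  expect_lt(max(abs(sm2$voxels[mask] - mean(ratio2[mask]))), 1e-3)
  expect_error(smooth_ratio_field(
    cbct_volume(array(NA_real_, dim = c(16, 16, 16)), grid, unit = "RATIO"),
    mask), class = "cbct_argument_error")
})

test_that("smoothing a checkerboard ratio matches a discrete convolution oracle", {
  n <- c(20, 20, 20)
  grid <- image_grid(n, c(1, 1, 1))
  idx <- expand.grid(i = 1:n[1], j = 1:n[2], k = 1:n[3])
  board <- array(ifelse((idx$i + idx$j + idx$k) %% 2 == 0, 0.9, 1.1), dim = n)
  mask <- array(TRUE, dim = n)
  rv <- cbct_volume(board, grid, unit = "RATIO")
  spec <- filter_spec(width_mm = 20)
  sm <- smooth_ratio_field(rv, mask, spec)
  interior <- array(FALSE, dim = n)
  interior[8:13, 8:13, 8:13] <- TRUE
  expect_lt(max(abs(sm$voxels[interior] - 1)), 1e-2)
  # oracle: explicit dense convolution of the weighted field at one voxel
  sigma <- 20 / (2 * sqrt(2 * log(2)))
  r <- ceiling(4 * sigma)
  off <- expand.grid(a = -r:r, b = -r:r, c = -r:r)
  w <- exp(-0.5 * (off$a^2 + off$b^2 + off$c^2) / sigma^2)
  centre <- c(10, 10, 10)
  ii <- centre[1] + off$a; jj <- centre[2] + off$b; kk <- centre[3] + off$c
  ok <- ii >= 1 & ii <= n[1] & jj >= 1 & jj <= n[2] & kk >= 1 & kk <= n[3]
  vals <- board[cbind(ii[ok], jj[ok], kk[ok])]
  oracle <- sum(w[ok] * vals) / sum(w[ok])
  expect_equal(sm$voxels[10, 10, 10], oracle, tolerance = 1e-10)
})

test_that("enhancement multiplies the CBCT by the filtered ratio on the mask", {
  grid <- image_grid(c(6, 6, 6))
  cb <- cbct_volume(array(0.8, dim = c(6, 6, 6)), grid, unit = "MU_RELATIVE")
  ratio <- cbct_volume(array(1.25, dim = c(6, 6, 6)), grid, unit = "RATIO")
  mask <- array(FALSE, dim = c(6, 6, 6)); mask[2:5, 2:5, 2:5] <- TRUE
  enh <- enhance_part(cb, ratio, mask)
  expect_equal(unique(as.numeric(enh$voxels[mask])), 1)
  expect_true(all(is.na(enh$voxels[!mask])))
  empty <- enhance_part(cb, ratio, array(FALSE, dim = c(6, 6, 6)))
  expect_true(all(is.na(empty$voxels)))
})

test_that("correcting a CT against itself is the identity within 1 HU", {
  fx <- std_fixture()
  res <- correct_cbct(fx$ct, fx$ct)
  expect_lt(max(abs(res$corrected$voxels - fx$ct$voxels)), 1)
})

test_that("voxels outside the FOV are completed from the planning CT exactly", {
  fx <- std_fixture()
  res <- std_correction()
  out <- !res$fov
  expect_gt(sum(out), 0)
  expect_identical(res$corrected$voxels[out], fx$ct$voxels[out])
})

test_that("a noiseless smooth multiplicative field is removed almost entirely", {
  # pure cupping (amplitude 0.15, 80 mm length scale), no shifts, no noise
  ph <- generate_phantom_ct(phantom_spec(seed = 1))
  spec <- degradation_spec(per_class_hu_shift = c(air = 0, lung = 0,
                                                  soft = 0, bone = 0),
                           arc_shading_amplitude = 0, noise_sd_hu = 0,
                           fov_radius_mm = Inf)
  deg <- degrade_to_cbct(ph$ct, ph$masks, spec)
  res <- correct_cbct(ph$ct, deg$cbct)
  masks <- ph$masks
  masks$fov <- res$fov
  e_orig <- hu_error_metrics(deg$cbct, ph$ct, masks)
  e_corr <- hu_error_metrics(res$corrected, ph$ct, masks)
  expect_gt(e_orig$mae_hu, 20)    # the cupping field is nontrivial
  expect_lte(e_corr$mae_hu, 0.3 * e_orig$mae_hu)
  expect_gte(e_corr$rmse_hu, e_corr$mae_hu)
})

test_that("a global attenuation scale on the CBCT is absorbed by the ratio", {
  fx <- std_fixture()
  res <- std_correction()
  scaled <- fx$cbct
  scaled$voxels <- (scaled$voxels + 1000) * 1.2 - 1000
  res_s <- correct_cbct(fx$ct, scaled, fx$truth_transform)
  body <- res$masks_ct$body
  expect_lt(max(abs(res_s$corrected$voxels[body] -
                      res$corrected$voxels[body])), 2)
})

test_that("noise-only degradation is not amplified by the correction", {
  ph <- small_phantom()
  dn <- degradation_spec(cupping_amplitude = 0, arc_shading_amplitude = 0,
                         per_class_hu_shift = c(air = 0, lung = 0,
                                                soft = 0, bone = 0),
                         noise_sd_hu = 15, fov_radius_mm = Inf, seed = 2)
  deg <- degrade_to_cbct(ph$ct, ph$masks, dn)
  res <- correct_cbct(ph$ct, deg$cbct)
  body <- ph$masks$body
  sd_orig <- sd(deg$cbct$voxels[body] - ph$ct$voxels[body])
  sd_corr <- sd(res$corrected$voxels[body] - ph$ct$voxels[body])
  expect_lte(sd_corr, 1.05 * sd_orig)
})

test_that("with a very wide filter each class mean is restored within 5 HU", {
  fx <- std_fixture()
  res <- correct_cbct(fx$ct, fx$cbct, fx$truth_transform,
                      spec = filter_spec(width_mm = 5000))
  for (cls in c("lung", "soft", "bone")) {
    joint <- res$masks_ct[[cls]] & res$masks_cbct[[cls]] & res$fov
    expect_lt(abs(mean(res$corrected$voxels[joint]) -
                    mean(fx$ct$voxels[joint])), 5)
  }
})

test_that("ratio fields stay inside the configured clamp bounds", {
  res <- std_correction()
  spec <- filter_spec()
  for (cls in c("lung", "soft", "bone")) {
    v <- res$ratio_fields[[cls]]$voxels
    v <- v[!is.na(v)]
    expect_true(all(v >= spec$ratio_floor & v <= spec$ratio_ceiling))
  }
})
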