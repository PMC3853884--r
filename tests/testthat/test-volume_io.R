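test_that("grid constructor validates geometry invariants", {
  expect_error(image_grid(c(8, 8, 0)), class = "cbct_argument_error")
  expect_error(image_grid(c(8, 8, 8), spacing = c(1, -1, 1)),
               class = "cbct_argument_error")
  bad_dir <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0.5, 1), 3, 3)
  expect_error(image_grid(c(8, 8, 8), direction = bad_dir),
               class = "cbct_argument_error")
  g <- image_grid(c(8, 8, 4), c(1, 1, 3), c(-10, 0, 5))
  expect_equal(world_to_voxel(g, voxel_to_world(g, cbind(3, 4, 2))),
               cbind(3, 4, 2), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("NIfTI round trip preserves voxels exactly and geometry to 1e-4 mm", {
  withr::local_seed(7)
  for (spacing in list(c(1, 1, 1), c(1, 1, 3))) {
    grid <- image_grid(c(16, 16, 16), spacing, origin = c(-12.5, 3.25, -40))
    vol <- cbct_volume(array(rnorm(16^3, -200, 300), dim = c(16, 16, 16)), grid)
    path <- withr::local_tempfile(fileext = ".nii.gz")
    write_volume(vol, path)
    back <- read_volume(path)
    expect_identical(back$voxels, vol$voxels)
    expect_equal(back$grid$spacing, spacing, tolerance = 1e-6)
    expect_lt(max(abs(back$grid$origin - grid$origin)), 1e-4)
    expect_lt(max(abs(back$grid$direction - grid$direction)), 1e-6)
  }
})

test_that("constant image round-trips and file is non-empty", {
  grid <- image_grid(c(16, 16, 16))
  vol <- cbct_volume(array(-1000, dim = c(16, 16, 16)), grid)
  path <- withr::local_tempfile(fileext = ".nii")
  write_volume(vol, path)
  expect_gt(file.size(path), 0)
  back <- read_volume(path)
  expect_identical(back$voxels, vol$voxels)
  expect_equal(back$grid$shape, grid$shape)
})

test_that("MetaImage round trip is lossless for both .mha and .mhd", {
  withr::local_seed(11)
  grid <- image_grid(c(12, 10, 8), c(0.9, 1.1, 3), c(5, -7, 2))
  vol <- cbct_volume(array(rnorm(12 * 10 * 8), dim = c(12, 10, 8)), grid)
  for (ext in c(".mha", ".mhd")) {
    path <- file.path(withr::local_tempdir(), paste0("vol", ext))
    write_volume(vol, path)
    back <- read_volume(path)
    expect_identical(back$voxels, vol$voxels)
    expect_lt(max(abs(back$grid$origin - grid$origin)), 1e-4)
    expect_equal(back$grid$spacing, grid$spacing, tolerance = 1e-9)
  }
})

test_that("intensity unit and padding survive a write/read round trip", {
  grid <- image_grid(c(6, 6, 6))
  ratio <- cbct_volume(array(1.25, dim = c(6, 6, 6)), grid, unit = "RATIO")
  for (ext in c(".nii.gz", ".mha")) {
    path <- file.path(withr::local_tempdir(), paste0("r", ext))
    write_volume(ratio, path)
    back <- read_volume(path)
    expect_identical(back$unit, "RATIO")
    expect_identical(back$padding, 1)
  }
})

test_that("non-3-D or unreadable inputs raise format errors naming the path", {
  path <- withr::local_tempfile(fileext = ".nii")
  img2d <- RNifti::asNifti(matrix(rnorm(64), 8, 8))
  RNifti::writeNifti(img2d, path)
  expect_error(read_volume(path), "not a 3-D image", class = "cbct_format_error")
  expect_error(read_volume("nope.nii"), class = "cbct_io_error")
  txt <- withr::local_tempfile(fileext = ".txt")
  writeLines("not an image", txt)
  expect_error(read_volume(txt), class = "cbct_format_error")
})

test_that("resampling with identity transform on the same grid is the identity", {
  ph <- small_phantom()
  out <- resample_to_grid(ph$ct, ph$ct$grid, rigid_transform(), "linear")
  expect_lt(max(abs(out$voxels - ph$ct$voxels)), 1e-6)
  expect_true(all(out$support))
})

test_that("a constant image stays constant under any rigid transform", {
  grid <- image_grid(c(20, 20, 10), c(2, 2, 2), c(-19, -19, -9))
  vol <- cbct_volume(array(100, dim = c(20, 20, 10)), grid)
  tr <- rigid_transform(c(2, -3, 5), c(4, 1, -2), c(0, 0, 0))
  out <- resample_to_grid(vol, grid, tr, "linear")
  expect_lt(max(abs(out$voxels[out$support] - 100)), 1e-9)
  expect_true(all(out$voxels[!out$support] == vol$padding))
})

test_that("nearest-neighbour resampling keeps masks binary", {
  ph <- small_phantom()
  lab <- cbct_volume(array(as.numeric(ph$masks$lung), dim = ph$ct$grid$shape),
                     ph$ct$grid, unit = "HU", padding = 0)
  tr <- rigid_transform(c(0, 0, 3), c(2.5, -1, 4), c(0, 0, 0))
  out <- resample_to_grid(lab, ph$ct$grid, tr, "nearest")
  expect_true(all(out$voxels %in% c(0, 1)))
})

test_that("HU mass is conserved when resampling 5 mm slices onto a 3 mm grid", {
  # 1-D smooth axial profile; oracle = trapezoidal integration of the profile
  n_src <- c(8, 8, 40)
  src_grid <- image_grid(n_src, c(2, 2, 5), c(0, 0, 0))
  zs <- (0:39) * 5
  prof <- 200 * exp(-((zs - 100) / 40)^2)
  vox <- array(rep(prof, each = 64), dim = n_src)
  src <- cbct_volume(vox, src_grid, padding = 0)
  n_ref <- c(8, 8, 66)
  ref <- image_grid(n_ref, c(2, 2, 3), c(0, 0, 0))
  out <- resample_to_grid(src, ref, rigid_transform(), "linear")
  mass_out <- (sum(out$voxels[1, 1, ]) - 0.5 * (out$voxels[1, 1, 1] +
                                                  out$voxels[1, 1, 66])) * 3
  oracle <- (sum(prof) - 0.5 * (prof[1] + prof[40])) * 5
  expect_lt(abs(mass_out - oracle) / oracle, 0.01)
})

test_that("forward then inverse resampling returns a smooth phantom within 2 HU", {
  spec <- small_phantom_spec()
  spec$texture_sd_hu <- 0
  ph <- generate_phantom_ct(spec)
  tr <- rigid_transform(c(0, 0, 2), c(3, -2, 1), c(0, 0, 0))
  fwd <- resample_to_grid(ph$ct, ph$ct$grid, tr, "linear")
  back <- resample_to_grid(fwd, ph$ct$grid, invert_transform(tr), "linear")
  # interiors only: the boundary shells see genuine interpolation loss
  core <- cbctcorr:::erode3d(ph$masks$lung, 2) |
    cbctcorr:::erode3d(ph$masks$soft, 2)
  core <- core & back$support
  expect_lt(mean(abs(back$voxels[core] - ph$ct$voxels[core])), 2)
})

test_that("degenerate reference grids are rejected", {
  ph <- small_phantom()
  bad <- ph$ct$grid
  bad$shape <- c(0L, 8L, 8L)
  expect_error(resample_to_grid(ph$ct, bad), class = "cbct_argument_error")
})

test_that("transform files round-trip and reject unknown keys", {
  tr <- rigid_transform(c(1.5, -2.25, 3), c(0.1, -0.2, 0.3), c(10, -20, 30))
  path <- withr::local_tempfile(fileext = ".txt")
  write_transform(tr, path)
  back <- read_transform(path)
  expect_equal(back$rotation_deg, tr$rotation_deg, tolerance = 1e-15)
  expect_equal(back$translation_mm, tr$translation_mm, tolerance = 1e-15)
  expect_equal(back$center_mm, tr$center_mm, tolerance = 1e-15)
  writeLines("wobble: 1 2 3", path)
  expect_error(read_transform(path), class = "cbct_format_error")
})

test_that("a translation-only transform file is accepted", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines("translation_mm: 5 0 -2", path)
  tr <- read_transform(path)
  expect_equal(tr$translation_mm, c(5, 0, -2))
  expect_equal(tr$rotation_deg, c(0, 0, 0))
})
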