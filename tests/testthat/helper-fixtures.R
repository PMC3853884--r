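# Shared fixtures. The small phantom renders the same physical anatomy as the
# default spec on a coarser (5 mm) grid, so geometry-dependent expectations
# carry over while tests stay fast. Expensive objects are memoised per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_phantom_spec <- function(seed = 1L) {
  phantom_spec(shape = c(64, 64, 32), spacing_mm = c(5, 5, 5), seed = seed)
}

small_phantom <- function(seed = 1L) {
  cached(paste0("small_phantom_", seed), generate_phantom_ct(small_phantom_spec(seed)))
}

# full-size standard fixture (128x128x64 at 2.5 mm), shared across test files
std_fixture <- function(seed = 1L) {
  cached(paste0("std_fixture_", seed), standard_fixture(seed = seed))
}

std_correction <- function(seed = 1L) {
  cached(paste0("std_correction_", seed), {
    fx <- std_fixture(seed)
    correct_cbct(fx$ct, fx$cbct, fx$truth_transform)
  })
}

# a small uniform-soft-tissue body on a coarse grid, for arithmetic tests
flat_body_volume <- function(n = c(24, 24, 12), spacing = c(5, 5, 5),
                             soft_hu = 40) {
  grid <- image_grid(n, spacing, -(n - 1) / 2 * spacing)
  co <- expand.grid(i = 0:(n[1] - 1), j = 0:(n[2] - 1), k = 0:(n[3] - 1))
  w <- voxel_to_world(grid, as.matrix(co))
  body <- array((w[, 1] / (n[1] * spacing[1] * 0.35))^2 +
                (w[, 2] / (n[2] * spacing[2] * 0.35))^2 +
                (w[, 3] / (n[3] * spacing[3] * 0.45))^2 <= 1, dim = n)
  vox <- array(-1000, dim = n)
  vox[body] <- soft_hu
  list(vol = cbct_volume(vox, grid), body = body)
}

# rotation angle (degrees) between two rigid transforms
rotation_error_deg <- function(a, b) {
  Ra <- cbctcorr:::rotation_matrix(a$rotation_deg)
  Rb <- cbctcorr:::rotation_matrix(b$rotation_deg)
  acos(pmin(pmax((sum(diag(crossprod(Ra, Rb))) - 1) / 2, -1), 1)) * 180 / pi
}

# displacement (mm) of the world origin between two transforms
translation_error_mm <- function(a, b) {
  sqrt(sum((transform_points(a, matrix(0, 1, 3)) -
              transform_points(b, matrix(0, 1, 3)))^2))
}
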