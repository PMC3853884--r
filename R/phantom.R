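#' Specification of the digital thorax/breast phantom
#'
#' An elliptical-torso phantom with two lungs, a spine column, rib spheres and
#' a left-breast protrusion, defined analytically in world millimetres so the
#' same anatomy can be rendered on any grid. Class HU means are air -1000,
#' lung -750, soft tissue +40, bone +700; lung/soft/bone voxels carry
#' independent Gaussian texture (air is uniform: sub-air HU is not physical).
#'
#' @param shape voxel counts (default 128 x 128 x 64).
#' @param spacing_mm voxel spacing (default 2.5 mm isotropic); the grid is
#'   centered on the world origin.
#' @param body_semiaxes_mm torso ellipsoid semi-axes (x,y,z).
#' @param lung_centers_mm 2 x 3 matrix of lung ellipsoid centers.
#' @param lung_semiaxes_mm lung ellipsoid semi-axes (shared).
#' @param spine_center_xy_mm,spine_radius_mm,spine_halflength_mm spine cylinder
#'   (axis along z).
#' @param rib_centers_mm n x 3 matrix of rib sphere centers.
#' @param rib_radius_mm rib sphere radius.
#' @param breast_center_mm,breast_semiaxes_mm left-breast hemi-ellipsoid
#'   (anterior half, y below center).
#' @param class_hu named HU means for air/lung/soft/bone.
#' @param texture_sd_hu intra-class HU texture standard deviation (default 20).
#' @param seed RNG seed for the texture.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128, 64),
                         spacing_mm = c(2.5, 2.5, 2.5),
                         body_semiaxes_mm = c(140, 95, 75),
                         lung_centers_mm = rbind(c(-55, -10, 5), c(55, -10, 5)),
                         lung_semiaxes_mm = c(45, 55, 55),
                         spine_center_xy_mm = c(0, 55),
                         spine_radius_mm = 10,
                         spine_halflength_mm = 50,
                         rib_centers_mm = rbind(c(-95, -30, -30), c(-95, -30, 0),
                                                c(-95, -30, 30), c(95, -30, -30),
                                                c(95, -30, 0), c(95, -30, 30)),
                         rib_radius_mm = 8,
                         breast_center_mm = c(60, -80, 0),
                         breast_semiaxes_mm = c(45, 45, 40),
                         class_hu = c(air = -1000, lung = -750, soft = 40, bone = 700),
                         texture_sd_hu = 20,
                         seed = 1L) {
  shape <- as.integer(shape)
  spacing_mm <- as.numeric(spacing_mm)
  origin <- -(shape - 1) / 2 * spacing_mm
  grid <- image_grid(shape, spacing_mm, origin)
  if (!all(c("air", "lung", "soft", "bone") %in% names(class_hu)))
    cbct_stop("cbct_argument_error", "class_hu must name air, lung, soft, bone")
  hu <- class_hu[c("air", "lung", "soft", "bone")]
  if (any(diff(hu) <= 0))
    cbct_stop("cbct_argument_error", "class HU means must be ordered air < lung < soft < bone")
  half <- (shape - 1) / 2 * spacing_mm
  if (any(body_semiaxes_mm > half + 1e-9))
    cbct_stop("cbct_specification_error", "body ellipsoid does not fit inside the grid")
  structure(list(grid = grid, body_semiaxes_mm = body_semiaxes_mm,
                 lung_centers_mm = lung_centers_mm,
                 lung_semiaxes_mm = lung_semiaxes_mm,
                 spine_center_xy_mm = spine_center_xy_mm,
                 spine_radius_mm = spine_radius_mm,
                 spine_halflength_mm = spine_halflength_mm,
                 rib_centers_mm = rib_centers_mm, rib_radius_mm = rib_radius_mm,
                 breast_center_mm = breast_center_mm,
                 breast_semiaxes_mm = breast_semiaxes_mm,
                 class_hu = hu, texture_sd_hu = texture_sd_hu,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# world coordinate arrays (one per axis) for an axis-aligned centered grid
grid_coords <- function(grid) {
  xs <- grid$origin[1] + (0:(grid$shape[1] - 1)) * grid$spacing[1]
  ys <- grid$origin[2] + (0:(grid$shape[2] - 1)) * grid$spacing[2]
  zs <- grid$origin[3] + (0:(grid$shape[3] - 1)) * grid$spacing[3]
  list(x = array(rep(xs, times = grid$shape[2] * grid$shape[3]), dim = grid$shape),
       y = array(rep(rep(ys, each = grid$shape[1]), times = grid$shape[3]),
                 dim = grid$shape),
       z = array(rep(zs, each = grid$shape[1] * grid$shape[2]), dim = grid$shape))
}

ellipsoid_mask <- function(co, center, semi) {
  ((co$x - center[1]) / semi[1])^2 + ((co$y - center[2]) / semi[2])^2 +
    ((co$z - center[3]) / semi[3])^2 <= 1
}

#' Render the phantom planning CT and its ground-truth masks
#'
#' Deterministic given `spec$seed`. Voxels are the class HU mean plus seeded
#' Gaussian texture (none in air), floored at -1000 HU; the returned masks are
#' the exact constructive geometry (a valid partition).
#'
#' @param spec a [phantom_spec].
#' @return A list with `ct` (a [cbct_volume], HU) and `masks`
#'   (a `tissue_mask_set`).
#' @export
generate_phantom_ct <- function(spec) {
  grid <- spec$grid
  co <- grid_coords(grid)
  body0 <- ellipsoid_mask(co, c(0, 0, 0), spec$body_semiaxes_mm)
  breast <- ellipsoid_mask(co, spec$breast_center_mm, spec$breast_semiaxes_mm) &
    (co$y <= spec$breast_center_mm[2])
  body <- body0 | breast
  lung <- ellipsoid_mask(co, spec$lung_centers_mm[1, ], spec$lung_semiaxes_mm) |
    ellipsoid_mask(co, spec$lung_centers_mm[2, ], spec$lung_semiaxes_mm)
  spine <- (co$x - spec$spine_center_xy_mm[1])^2 +
    (co$y - spec$spine_center_xy_mm[2])^2 <= spec$spine_radius_mm^2
  spine <- spine & abs(co$z) <= spec$spine_halflength_mm
  bone <- spine
  for (r in seq_len(nrow(spec$rib_centers_mm))) {
    ctr <- spec$rib_centers_mm[r, ]
    bone <- bone | (((co$x - ctr[1])^2 + (co$y - ctr[2])^2 + (co$z - ctr[3])^2)
                    <= spec$rib_radius_mm^2)
  }
  if (any(lung & !body0) || any(bone & !body0))
    cbct_stop("cbct_specification_error", "lung/bone structures extend outside the body")
  bone <- bone & !lung
  soft <- body & !lung & !bone
  air <- !body
  vox <- array(spec$class_hu[["air"]], dim = grid$shape)
  vox[lung] <- spec$class_hu[["lung"]]
  vox[soft] <- spec$class_hu[["soft"]]
  vox[bone] <- spec$class_hu[["bone"]]
  if (spec$texture_sd_hu > 0) {
    tissue <- which(body)
    tex <- with_seed(spec$seed, rnorm(length(tissue), 0, spec$texture_sd_hu))
    vox[tissue] <- vox[tissue] + tex
  }
  vox <- pmax(vox, -1000)
  ct <- cbct_volume(vox, grid, unit = "HU")
  masks <- new_tissue_mask_set(air, lung, soft, bone, body,
                               array(TRUE, dim = grid$shape), grid)
  validate_partition(masks)
  list(ct = ct, masks = masks)
}

#' Specification of the simulated CBCT degradation
#'
#' All effects a partial-arc breast CBCT adds on top of the planning-CT
#' anatomy: a multiplicative radial cupping field (darker core, scatter
#' surrogate) on the attenuation scale, a smooth angular shading surrogate for
#' the 200-degree acquisition arc, additive per-class HU bias, voxel noise,
#' and cylindrical field-of-view truncation.
#'
#' @param cupping_amplitude fractional attenuation loss at the cylinder axis
#'   (default 0.15).
#' @param cupping_length_mm Gaussian length scale of the cupping field
#'   (default 80 mm).
#' @param per_class_hu_shift named HU offsets added per tissue class
#'   (defaults: air 0, lung -30, soft -40, bone -60).
#' @param arc_shading_amplitude peak fractional shading opposite the scanned
#'   arc (default 0.05).
#' @param arc_span_deg angular span of the acquisition arc (default 200).
#' @param noise_sd_hu additive Gaussian noise SD in HU (default 15).
#' @param fov_radius_mm radius of the reconstructed cylinder (default 110 mm,
#'   covering roughly 70% of the default phantom body); `Inf` disables
#'   truncation.
#' @param seed RNG seed for the noise.
#' @return An object of class `degradation_spec`.
#' @export
degradation_spec <- function(cupping_amplitude = 0.15, cupping_length_mm = 80,
                             per_class_hu_shift = c(air = 0, lung = -30,
                                                    soft = -40, bone = -60),
                             arc_shading_amplitude = 0.05, arc_span_deg = 200,
                             noise_sd_hu = 15, fov_radius_mm = 110, seed = 1L) {
  if (cupping_amplitude < 0 || cupping_amplitude > 0.5 ||
      arc_shading_amplitude < 0 || arc_shading_amplitude > 0.5)
    cbct_stop("cbct_argument_error", "field amplitudes must lie in [0, 0.5]")
  if (fov_radius_mm <= 0)
    cbct_stop("cbct_argument_error", "fov_radius_mm must be positive")
  if (!all(c("air", "lung", "soft", "bone") %in% names(per_class_hu_shift)))
    cbct_stop("cbct_argument_error", "per_class_hu_shift must name air, lung, soft, bone")
  structure(list(cupping_amplitude = cupping_amplitude,
                 cupping_length_mm = cupping_length_mm,
                 per_class_hu_shift = per_class_hu_shift,
                 arc_shading_amplitude = arc_shading_amplitude,
                 arc_span_deg = arc_span_deg, noise_sd_hu = noise_sd_hu,
                 fov_radius_mm = fov_radius_mm, seed = as.integer(seed)),
            class = "degradation_spec")
}

#' Degrade a planning CT into a synthetic CBCT
#'
#' On the attenuation scale (HU + 1000), the image is multiplied by the
#' cupping and arc-shading fields; the realized multiplicative bias field is
#' returned as ground truth. Per-class HU shifts and seeded Gaussian noise are
#' then added, and voxels outside the cylindrical FOV (axis along z through
#' the grid center) are set to -1000 and excluded from the `fov` mask.
#' Deterministic given `spec$seed`; with all amplitudes, shifts and noise at
#' zero and an infinite FOV the input is returned bit-identically.
#'
#' @param ct a [cbct_volume] in HU.
#' @param truth_masks the phantom's `tissue_mask_set` (per-class shifts).
#' @param spec a [degradation_spec].
#' @return A list with `cbct` (a [cbct_volume]), `bias` (RATIO-unit
#'   [cbct_volume], the multiplicative field), and `fov` (logical array).
#' @export
degrade_to_cbct <- function(ct, truth_masks, spec = degradation_spec()) {
  if (ct$unit != "HU")
    cbct_stop("cbct_argument_error", "degradation requires an HU image")
  grid <- ct$grid
  co <- grid_coords(grid)
  ctr <- voxel_to_world(grid, matrix((grid$shape - 1) / 2, 1))
  dx <- co$x - ctr[1]; dy <- co$y - ctr[2]
  r2 <- dx^2 + dy^2
  cup <- 1 - spec$cupping_amplitude * exp(-r2 / (2 * spec$cupping_length_mm^2))
  if (spec$arc_shading_amplitude > 0) {
    # shading is strongest toward the center of the un-scanned angular gap
    theta <- atan2(dy, dx)
    gap_center <- pi / 2   # posterior, opposite a 200-degree anterior arc
    arc <- 1 - spec$arc_shading_amplitude * ((1 + cos(theta - gap_center)) / 2)
  } else {
    arc <- 1
  }
  bias <- cup * arc
  if (all(bias == 1)) hu <- ct$voxels
  else hu <- pmax(ct$voxels + 1000, 0) * bias - 1000
  shifts <- spec$per_class_hu_shift
  for (cls in c("air", "lung", "soft", "bone")) {
    s <- shifts[[cls]]
    if (s != 0) hu[truth_masks[[cls]]] <- hu[truth_masks[[cls]]] + s
  }
  if (spec$noise_sd_hu > 0) {
    hu <- hu + array(with_seed(spec$seed,
                               rnorm(length(hu), 0, spec$noise_sd_hu)),
                     dim = dim(hu))
  }
  if (is.finite(spec$fov_radius_mm)) {
    fov <- array(r2 <= spec$fov_radius_mm^2, dim = grid$shape)
    hu[!fov] <- -1000
  } else {
    fov <- array(TRUE, dim = grid$shape)
  }
  bias_vol <- cbct_volume(array(bias, dim = grid$shape), grid, unit = "RATIO")
  list(cbct = cbct_volume(hu, grid, unit = "HU"), bias = bias_vol, fov = fov)
}

#' Standard phantom + degraded CBCT fixture
#'
#' Default [phantom_spec()] and [degradation_spec()] plus a fixed rigid offset
#' (3, -2, 1) mm and 2 degrees about the axial (z) axis: the clean CT is
#' resampled into the offset CBCT frame and then degraded there (cupping, arc
#' shading and FOV truncation are scanner-frame effects). Registering the
#' returned `cbct` to `ct` should recover `truth_transform`.
#'
#' @param seed integer seed driving both texture and noise.
#' @param shape,spacing_mm grid of the rendered phantom (defaults 128x128x64
#'   at 2.5 mm).
#' @param degradation optional [degradation_spec()] override (its `seed` is
#'   replaced by `seed + 1`).
#' @return A list: `ct`, `cbct` ([cbct_volume]s), `masks` (ground truth, CT
#'   frame), `masks_cbct_frame` (ground truth moved to the CBCT frame),
#'   `truth_transform` ([rigid_transform], CBCT world -> CT world),
#'   `truth_bias` (RATIO volume, CBCT frame), `fov` (logical array, CBCT
#'   frame), and the two specs.
#' @export
standard_fixture <- function(seed = 1L, shape = c(128, 128, 64),
                             spacing_mm = c(2.5, 2.5, 2.5),
                             degradation = NULL) {
  pspec <- phantom_spec(shape = shape, spacing_mm = spacing_mm, seed = seed)
  if (is.null(degradation)) degradation <- degradation_spec(seed = seed + 1L)
  else degradation$seed <- seed + 1L
  ph <- generate_phantom_ct(pspec)
  truth <- rigid_transform(rotation_deg = c(0, 0, 2),
                           translation_mm = c(3, -2, 1),
                           center_mm = c(0, 0, 0))
  inv <- invert_transform(truth)
  ct_moved <- resample_to_grid(ph$ct, ph$ct$grid, inv, "linear")
  masks_moved <- move_masks(ph$masks, ph$ct$grid, inv)
  deg <- degrade_to_cbct(ct_moved, masks_moved, degradation)
  list(ct = ph$ct, cbct = deg$cbct, masks = ph$masks,
       masks_cbct_frame = masks_moved, truth_transform = truth,
       truth_bias = deg$bias, fov = deg$fov,
       phantom_spec = pspec, degradation_spec = degradation)
}

# nearest-neighbour transport of a tissue_mask_set onto a grid
# (labels: 0 air, 1 lung, 2 soft, 3 bone; body = lung|soft|bone)
move_masks <- function(masks, grid, transform) {
  lab <- masks_to_labels(masks)
  lab_m <- resample_to_grid(lab, grid, transform, "nearest")
  v <- lab_m$voxels
  sup <- lab_m$support
  air <- (v == 0) | !sup
  out <- new_tissue_mask_set(air, sup & v == 1, sup & v == 2, sup & v == 3,
                             sup & v > 0, array(TRUE, dim = grid$shape), grid)
  validate_partition(out)
  out
}
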