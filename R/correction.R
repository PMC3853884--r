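#' Ratio-field filter settings
#'
#' Controls the per-class ratio images: the attenuation offset used to map HU
#' onto a strictly positive scale, clamping bounds for the voxelwise ratio,
#' and the low-pass filter that removes high-spatial-frequency content before
#' the ratio multiplies the CBCT back.
#'
#' @param kind `"gaussian"` (default) or `"median"` is reserved; only the
#'   Gaussian filter is implemented (scatter fields are smooth at the
#'   several-cm scale).
#' @param width_mm Gaussian full width at half maximum in mm (default 20).
#' @param ratio_floor,ratio_ceiling clamp bounds for the ratio (defaults 0.2
#'   and 5): residual misregistration at tissue interfaces produces extreme
#'   quotients whose influence must stay bounded.
#' @param mu_offset_hu HU offset of the attenuation-proportional scale
#'   (default 1000, i.e. (HU+1000)/1000 with air at 0 and water at 1).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = "gaussian", width_mm = 20,
                        ratio_floor = 0.2, ratio_ceiling = 5,
                        mu_offset_hu = 1000) {
  kind <- match.arg(kind, c("gaussian"))
  if (width_mm <= 0)
    cbct_stop("cbct_argument_error", "width_mm must be positive")
  if (!(ratio_floor > 0 && ratio_floor < 1 && ratio_ceiling > 1))
    cbct_stop("cbct_argument_error", "need 0 < ratio_floor < 1 < ratio_ceiling")
  structure(list(kind = kind, width_mm = width_mm, ratio_floor = ratio_floor,
                 ratio_ceiling = ratio_ceiling, mu_offset_hu = mu_offset_hu),
            class = "filter_spec")
}

#' Convert HU to the relative attenuation scale
#'
#' `mu = max((HU + mu_offset_hu) / mu_offset_hu, 0)`: air maps to 0, water to
#' 1. Ratio images are formed on this scale because HU cross zero and their
#' raw quotient is ill-defined.
#'
#' @param img a [cbct_volume] in HU.
#' @param mu_offset_hu scale offset (default 1000).
#' @return A `MU_RELATIVE` [cbct_volume].
#' @export
hu_to_mu <- function(img, mu_offset_hu = 1000) {
  if (img$unit != "HU")
    cbct_stop("cbct_argument_error", "hu_to_mu expects an HU image")
  v <- pmax((img$voxels + mu_offset_hu) / mu_offset_hu, 0)
  out <- cbct_volume(array(v, dim = dim(img$voxels)), img$grid,
                     unit = "MU_RELATIVE", padding = 0)
  out$support <- img$support
  out
}

#' Convert relative attenuation back to HU
#' @param img a `MU_RELATIVE` [cbct_volume].
#' @param mu_offset_hu scale offset used by [hu_to_mu()].
#' @return An HU [cbct_volume]; exact inverse of [hu_to_mu()] for HU >= -1000.
#' @export
mu_to_hu <- function(img, mu_offset_hu = 1000) {
  if (img$unit != "MU_RELATIVE")
    cbct_stop("cbct_argument_error", "mu_to_hu expects a MU_RELATIVE image")
  v <- img$voxels * mu_offset_hu - mu_offset_hu
  out <- cbct_volume(array(v, dim = dim(img$voxels)), img$grid, unit = "HU")
  out$support <- img$support
  out
}

#' Per-class ratio image (planning CT over CBCT)
#'
#' Within `class_mask`, `ratio = ct / max(cbct, 1e-3)` on the attenuation
#' scale, clamped to `[ratio_floor, ratio_ceiling]`; `NA` (undefined) outside
#' the mask. An empty mask returns an all-undefined field with a warning (a
#' tissue class can be absent from a small field of view).
#'
#' @param ct_mu,cbct_mu `MU_RELATIVE` [cbct_volume]s on the same grid.
#' @param class_mask logical array: the joint (CT class AND CBCT class) mask
#'   of one tissue class.
#' @param spec a [filter_spec].
#' @return A RATIO [cbct_volume] with `NA` outside `class_mask`.
#' @export
compute_ratio_field <- function(ct_mu, cbct_mu, class_mask, spec = filter_spec()) {
  if (ct_mu$unit != "MU_RELATIVE" || cbct_mu$unit != "MU_RELATIVE")
    cbct_stop("cbct_argument_error", "ratio images are computed on the MU_RELATIVE scale")
  check_same_grid(ct_mu, cbct_mu)
  ratio <- array(NA_real_, dim = dim(ct_mu$voxels))
  if (!any(class_mask)) {
    warning("empty class mask: ratio field is undefined everywhere")
    out <- cbct_volume(ratio, ct_mu$grid, unit = "RATIO")
    return(out)
  }
  idx <- which(class_mask)
  r <- ct_mu$voxels[idx] / pmax(cbct_mu$voxels[idx], 1e-3)
  ratio[idx] <- pmin(pmax(r, spec$ratio_floor), spec$ratio_ceiling)
  cbct_volume(ratio, ct_mu$grid, unit = "RATIO")
}

#' Low-pass filter a masked ratio field (mask-normalized smoothing)
#'
#' Gaussian smoothing of the mask-weighted values divided by the smoothed mask
#' weights, evaluated over `target_mask`, so ratios never leak across class
#' boundaries. Where the smoothed weight underflows (isolated target regions
#' far from any defined ratio) the defined-region mean is used. The result is
#' clamped to the filter's ratio bounds.
#'
#' @param ratio a RATIO [cbct_volume] with `NA` where undefined.
#' @param target_mask logical array on which the output must be defined.
#' @param spec a [filter_spec] (FWHM `width_mm`).
#' @return A RATIO [cbct_volume] defined (non-`NA`) on all of `target_mask`.
#' @export
smooth_ratio_field <- function(ratio, target_mask, spec = filter_spec()) {
  if (ratio$unit != "RATIO")
    cbct_stop("cbct_argument_error", "smooth_ratio_field expects a RATIO image")
  defined <- !is.na(ratio$voxels)
  if (!any(defined))
    cbct_stop("cbct_argument_error", "ratio field is undefined everywhere")
  dims <- dim(ratio$voxels)
  sigma_vox <- (spec$width_mm / (2 * sqrt(2 * log(2)))) / ratio$grid$spacing
  w <- array(0, dims); w[defined] <- 1
  v <- array(0, dims); v[defined] <- ratio$voxels[defined]
  num <- cpp_gauss3(as.numeric(v), as.integer(dims), sigma_vox)
  den <- cpp_gauss3(as.numeric(w), as.integer(dims), sigma_vox)
  fallback <- mean(ratio$voxels[defined])
  sm <- ifelse(den > 1e-8, num / pmax(den, 1e-300), fallback)
  sm <- pmin(pmax(sm, spec$ratio_floor), spec$ratio_ceiling)
  out <- array(NA_real_, dims)
  out[target_mask] <- sm[target_mask]
  cbct_volume(out, ratio$grid, unit = "RATIO")
}

#' Multiply a CBCT part by its filtered ratio field
#'
#' `enhanced = smoothed_ratio * cbct` on `part_mask`, undefined (`NA`)
#' elsewhere: the per-class enhancement step before recombination.
#'
#' @param cbct_mu a `MU_RELATIVE` [cbct_volume].
#' @param smoothed_ratio a RATIO [cbct_volume] defined on `part_mask`.
#' @param part_mask logical array selecting the class.
#' @return A `MU_RELATIVE` [cbct_volume] defined on `part_mask`.
#' @export
enhance_part <- function(cbct_mu, smoothed_ratio, part_mask) {
  check_same_grid(cbct_mu, smoothed_ratio)
  out <- array(NA_real_, dim = dim(cbct_mu$voxels))
  idx <- which(part_mask)
  if (length(idx))
    out[idx] <- smoothed_ratio$voxels[idx] * cbct_mu$voxels[idx]
  cbct_volume(out, cbct_mu$grid, unit = "MU_RELATIVE", padding = 0)
}

#' Correct a CBCT using the planning CT as prior
#'
#' Full pipeline: (1) resample the CBCT onto the planning-CT grid through the
#' rigid transform, recording the field-of-view support; (2) normalize the
#' CBCT's global attenuation gain over the FOV (a geometric region, so the
#' step is exactly scale-equivariant); (3) segment both images into air /
#' lung / soft / bone; (4) per class, estimate the low-pass-filtered ratio
#' field over the joint (CT-class AND CBCT-class AND FOV) mask as the
#' quotient of the two mask-smoothed attenuation fields (normalized
#' convolution; exact for constant ratios and free of the noise bias that
#' inflates a smoothed voxelwise quotient), evaluated over the CBCT-class
#' region (the air part uses a unit ratio: its attenuation quotient is 0/0);
#' (5) multiply each
#' filtered ratio with the CBCT part and recombine using the CBCT masks (the
#' anatomy of the day); (6) convert back to HU and fill every voxel outside
#' the FOV from the planning CT exactly.
#'
#' If a tissue class is present in the CBCT but the joint mask is empty, its
#' ratio falls back to the soft-tissue mean ratio (graceful degradation for
#' small fields of view).
#'
#' @param ct planning CT, a [cbct_volume] in HU.
#' @param cbct CBCT, a [cbct_volume] in HU (its own grid/frame).
#' @param transform a [rigid_transform] mapping CBCT world coordinates into CT
#'   world coordinates; identity by default; `NULL` triggers rigid
#'   registration with `registration` settings.
#' @param thresholds a [segmentation_thresholds].
#' @param spec a [filter_spec].
#' @param fov optional logical array (CT grid) overriding the detected CBCT
#'   support; by default the support is the resampled footprint of voxels that
#'   are not padding in the CBCT.
#' @param registration a [registration_settings], used only when `transform`
#'   is `NULL`.
#' @return An object of class `cbct_correction`: `corrected` (HU volume on
#'   the CT grid), `ratio_fields` (list of four RATIO volumes), `masks_ct`,
#'   `masks_cbct`, `transform`, `fov`, `gain`, and `config`.
#' @export
correct_cbct <- function(ct, cbct, transform = rigid_transform(),
                         thresholds = segmentation_thresholds(),
                         spec = filter_spec(), fov = NULL,
                         registration = registration_settings()) {
  if (ct$unit != "HU" || cbct$unit != "HU")
    cbct_stop("cbct_argument_error", "ct and cbct must be HU images")
  if (is.null(transform))
    transform <- register_rigid(ct, cbct, registration)$transform
  cbct_r <- resample_to_grid(cbct, ct$grid, transform, "linear")
  support <- cbct_r$support
  # FOV: resampled footprint of reconstructed (non-padding) CBCT voxels
  ind <- cbct_volume(array(as.numeric(cbct$voxels != cbct$padding),
                           dim = dim(cbct$voxels)), cbct$grid,
                     unit = "HU", padding = 0)
  fov_detected <- support & (resample_to_grid(ind, ct$grid, transform,
                                              "nearest")$voxels > 0.5)
  fov <- if (is.null(fov)) fov_detected else (fov & support)
  if (!any(fov))
    cbct_stop("cbct_overlap_error", "CT and CBCT supports do not overlap")
  ct_mu <- hu_to_mu(ct, spec$mu_offset_hu)
  cb_mu <- hu_to_mu(cbct_r, spec$mu_offset_hu)
  # global gain normalization over the (purely geometric) FOV region
  mref <- mean(ct_mu$voxels[fov])
  mcb <- mean(cb_mu$voxels[fov])
  gain <- if (is.finite(mref / mcb) && mcb > 0) mref / mcb else 1
  cb_mu$voxels <- cb_mu$voxels * gain
  # segment both images; the CBCT is segmented after gain correction
  body_ct <- compute_body_mask(ct, thresholds$body_threshold_hu)
  masks_ct <- segment_tissues(ct, thresholds, body_ct)
  cb_hu_n <- mu_to_hu(cb_mu, spec$mu_offset_hu)
  body_cb <- compute_body_mask(cb_hu_n, thresholds$body_threshold_hu)
  body_cb <- body_cb & fov
  masks_cb <- segment_tissues(cb_hu_n, thresholds, body_cb)
  masks_cb <- suppress_fov_edge(masks_cb, fov)
  masks_ct$fov <- fov
  masks_cb$fov <- fov
  # per-class ratio estimation, enhancement, and recombination
  classes <- c("air", "lung", "soft", "bone")
  soft_joint <- masks_ct$soft & masks_cb$soft & fov
  soft_mean_ratio <- if (any(soft_joint)) {
    r <- ct_mu$voxels[soft_joint] / pmax(cb_mu$voxels[soft_joint], 1e-3)
    mean(pmin(pmax(r, spec$ratio_floor), spec$ratio_ceiling))
  } else 1
  corrected_mu <- array(0, dim = ct$grid$shape)
  ratio_fields <- list()
  for (cls in classes) {
    target <- masks_cb[[cls]] & fov
    if (!any(target)) {
      ratio_fields[[cls]] <- cbct_volume(array(NA_real_, dim = ct$grid$shape),
                                         ct$grid, unit = "RATIO")
      next
    }
    joint <- masks_ct[[cls]] & target
    if (cls == "air") {
      # air carries no attenuation signal: the planningCT/CBCT quotient is
      # 0/0 on the MU scale (and -1000/-1000 = 1 in raw HU), so the air part
      # passes through with unit ratio; this also protects body-boundary
      # voxels misassigned to air by either segmentation
      sm <- array(NA_real_, dim = ct$grid$shape)
      sm[target] <- 1
      sm <- cbct_volume(sm, ct$grid, unit = "RATIO")
    } else if (any(joint)) {
      sm <- smoothed_ratio_estimate(ct_mu, cb_mu, joint, target, spec)
    } else {
      # class absent from the joint mask: fall back to the soft-tissue mean
      sm <- array(NA_real_, dim = ct$grid$shape)
      sm[target] <- soft_mean_ratio
      sm <- cbct_volume(sm, ct$grid, unit = "RATIO")
    }
    enh <- enhance_part(cb_mu, sm, target)
    corrected_mu[target] <- enh$voxels[target]
    ratio_fields[[cls]] <- sm
  }
  corrected <- array(corrected_mu * spec$mu_offset_hu - spec$mu_offset_hu,
                     dim = ct$grid$shape)
  corrected[!fov] <- ct$voxels[!fov]   # FOV completion: exact copy of the CT
  corrected <- cbct_volume(corrected, ct$grid, unit = "HU")
  structure(list(corrected = corrected, ratio_fields = ratio_fields,
                 masks_ct = masks_ct, masks_cbct = masks_cb,
                 transform = transform, fov = fov, support = support,
                 gain = gain,
                 config = list(thresholds = unclass(thresholds),
                               filter = unclass(spec))),
            class = "cbct_correction")
}

# Filtered ratio field as a quotient of the two mask-smoothed attenuation
# fields (normalized convolution): exact for constant ratios, linear in the
# CBCT (so global gains cancel exactly), and -- unlike smoothing the voxelwise
# quotient -- free of the Jensen noise inflation that biases mean(x/y) upward
# in low-attenuation classes. Defined over target_mask; clamped.
smoothed_ratio_estimate <- function(ct_mu, cbct_mu, joint_mask, target_mask,
                                    spec) {
  dims <- dim(ct_mu$voxels)
  sigma_vox <- (spec$width_mm / (2 * sqrt(2 * log(2)))) / ct_mu$grid$spacing
  w <- array(0, dims); w[joint_mask] <- 1
  gx <- cpp_gauss3(as.numeric(ct_mu$voxels * w), as.integer(dims), sigma_vox)
  gy <- cpp_gauss3(as.numeric(cbct_mu$voxels * w), as.integer(dims), sigma_vox)
  gw <- cpp_gauss3(as.numeric(w), as.integer(dims), sigma_vox)
  fallback <- mean(ct_mu$voxels[joint_mask]) /
    max(mean(cbct_mu$voxels[joint_mask]), 1e-3)
  defined <- gw > 1e-8 & gy > 1e-8 * gw
  sm <- ifelse(defined, gx / pmax(gy, 1e-300), fallback)
  sm <- pmin(pmax(sm, spec$ratio_floor), spec$ratio_ceiling)
  out <- array(NA_real_, dims)
  out[target_mask] <- sm[target_mask]
  cbct_volume(out, ct_mu$grid, unit = "RATIO")
}

# remove lung/bone eligibility in a thin ring at the FOV boundary, where
# partial-object truncation makes thresholds unreliable
suppress_fov_edge <- function(masks, fov, ring_voxels = 2) {
  if (all(fov)) return(masks)
  interior <- erode3d(fov, ring_voxels, outside = FALSE)
  ring <- fov & !interior
  for (cls in c("lung", "bone")) {
    move <- masks[[cls]] & ring
    if (any(move)) {
      masks[[cls]] <- masks[[cls]] & !move
      masks$soft <- masks$soft | move
    }
  }
  validate_partition(masks)
  masks
}

#' @export
format.cbct_correction <- function(x, ...) {
  sprintf("<cbct_correction %s, gain %.4f, fov %.1f%%>",
          paste(x$corrected$grid$shape, collapse = "x"), x$gain,
          100 * mean(x$fov))
}

#' @export
print.cbct_correction <- function(x, ...) { cat(format(x), "\n"); invisible(x) }
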