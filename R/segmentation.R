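#' Threshold set for four-class tissue segmentation
#'
#' HU thresholds splitting the body interior into lung / soft tissue / bone,
#' plus the body-surface threshold and a minimum component volume below which
#' lung or bone specks are reassigned to soft tissue. Inside the body the soft
#' range is the closed interval `[lung_upper_hu, bone_lower_hu]`; everything
#' outside the body is air. Values are configurable because the thresholds are
#' empirical; the defaults are standard thoracic HU ranges.
#'
#' @param lung_upper_hu HU below which an in-body voxel is lung (default -400).
#' @param bone_lower_hu HU above which an in-body voxel is bone (default +200).
#' @param body_threshold_hu HU above which a voxel can belong to the body
#'   surface component (default -500).
#' @param min_component_mm3 minimum connected-component volume (mm^3) for lung
#'   and bone (default 500).
#' @return An object of class `segmentation_thresholds`.
#' @export
segmentation_thresholds <- function(lung_upper_hu = -400, bone_lower_hu = 200,
                                    body_threshold_hu = -500,
                                    min_component_mm3 = 500) {
  if (!(lung_upper_hu <= bone_lower_hu))
    cbct_stop("cbct_argument_error", "thresholds must satisfy lung_upper_hu <= bone_lower_hu")
  if (min_component_mm3 < 0)
    cbct_stop("cbct_argument_error", "min_component_mm3 must be >= 0")
  structure(list(lung_upper_hu = lung_upper_hu, bone_lower_hu = bone_lower_hu,
                 body_threshold_hu = body_threshold_hu,
                 min_component_mm3 = min_component_mm3),
            class = "segmentation_thresholds")
}

ball_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  keep <- g$x^2 + g$y^2 + g$z^2 <= radius^2 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

dilate3d <- function(mask, radius) {
  array(cpp_morph(as.logical(mask), as.integer(dim(mask)),
                  ball_offsets(radius), TRUE, FALSE), dim = dim(mask))
}

erode3d <- function(mask, radius, outside = TRUE) {
  array(cpp_morph(as.logical(mask), as.integer(dim(mask)),
                  ball_offsets(radius), FALSE, outside), dim = dim(mask))
}

label_components <- function(mask, connectivity = 6L) {
  array(cpp_label3d(as.logical(mask), as.integer(dim(mask)),
                    as.integer(connectivity)), dim = dim(mask))
}

largest_component <- function(mask) {
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L], n)
  lab == which.max(sizes)
}

#' Extract the patient body mask from an HU image
#'
#' Largest 6-connected component of voxels above `body_threshold_hu`,
#' morphologically closed with a 3-voxel-radius ball and hole-filled per axial
#' slice. Separates external air from internal low-HU tissue (lung), which raw
#' thresholds cannot do.
#'
#' @param img a [cbct_volume] in HU.
#' @param body_threshold_hu surface threshold (default -500 HU).
#' @return A logical array on `img`'s grid.
#' @export
compute_body_mask <- function(img, body_threshold_hu = -500) {
  if (img$unit != "HU")
    cbct_stop("cbct_argument_error", "body mask requires an HU image")
  raw <- img$voxels > body_threshold_hu
  if (!any(raw))
    cbct_stop("cbct_segmentation_error",
              sprintf("no voxel above the body threshold (%g HU)", body_threshold_hu))
  body <- largest_component(raw)
  body <- erode3d(dilate3d(body, 3), 3, outside = FALSE) # closing
  array(cpp_fill_holes_slices(as.logical(body), as.integer(dim(body))),
        dim = dim(body))
}

new_tissue_mask_set <- function(air, lung, soft, bone, body, fov, grid) {
  structure(list(air = air, lung = lung, soft = soft, bone = bone,
                 body = body, fov = fov, grid = grid),
            class = "tissue_mask_set")
}

#' @export
format.tissue_mask_set <- function(x, ...) {
  n <- prod(x$grid$shape)
  sprintf("<tissue_mask_set %s: air %.1f%%, lung %.1f%%, soft %.1f%%, bone %.1f%%>",
          paste(x$grid$shape, collapse = "x"),
          100 * sum(x$air) / n, 100 * sum(x$lung) / n,
          100 * sum(x$soft) / n, 100 * sum(x$bone) / n)
}

#' @export
print.tissue_mask_set <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Check that four class masks partition the grid
#' @param masks a `tissue_mask_set`.
#' @return `TRUE` invisibly; error if the masks overlap or leave gaps.
#' @export
validate_partition <- function(masks) {
  total <- masks$air + masks$lung + masks$soft + masks$bone
  if (any(total != 1L))
    cbct_stop("cbct_segmentation_error",
              "class masks do not partition the grid (overlap or gap)")
  invisible(TRUE)
}

#' Four-class tissue segmentation of an HU image
#'
#' Voxels outside the body mask are air. Inside the body, HU below
#' `lung_upper_hu` is lung, above `bone_lower_hu` bone, otherwise soft tissue;
#' lung/bone components smaller than `min_component_mm3` are reassigned to
#' soft tissue (see [clean_masks()]). The four masks always partition the grid.
#' Internal gas cavities land in the lung class (attenuation-equivalent).
#'
#' @param img a [cbct_volume] in HU.
#' @param thresholds a [segmentation_thresholds].
#' @param body logical body mask on the same grid (from [compute_body_mask()]).
#' @return A `tissue_mask_set` with fields `air`, `lung`, `soft`, `bone`,
#'   `body`, `fov` (all `TRUE` here) and `grid`.
#' @export
segment_tissues <- function(img, thresholds = segmentation_thresholds(), body) {
  if (img$unit != "HU")
    cbct_stop("cbct_argument_error", "segmentation requires an HU image")
  if (!identical(dim(body), dim(img$voxels)))
    cbct_stop("cbct_argument_error", "body mask shape does not match image")
  v <- img$voxels
  lung <- body & (v < thresholds$lung_upper_hu)
  bone <- body & (v > thresholds$bone_lower_hu)
  soft <- body & !lung & !bone
  air <- !body
  masks <- new_tissue_mask_set(air, lung, soft, bone, body,
                               array(TRUE, dim = dim(v)), img$grid)
  masks <- clean_masks(masks, thresholds$min_component_mm3)
  validate_partition(masks)
  masks
}

#' Reassign small lung/bone components to soft tissue
#'
#' Connected components (6-connectivity) of the lung and bone masks whose
#' volume falls below `min_component_mm3` are moved to the soft-tissue class,
#' suppressing threshold speckle; the partition invariant is preserved.
#'
#' @param masks a `tissue_mask_set`.
#' @param min_component_mm3 volume floor in mm^3.
#' @return The cleaned `tissue_mask_set`.
#' @export
clean_masks <- function(masks, min_component_mm3 = 500) {
  voxvol <- prod(masks$grid$spacing)
  for (cls in c("lung", "bone")) {
    m <- masks[[cls]]
    if (!any(m)) next
    lab <- label_components(m)
    sizes <- tabulate(lab[lab > 0L], max(lab))
    small <- which(sizes * voxvol < min_component_mm3)
    if (length(small)) {
      drop <- array(lab %in% small, dim = dim(m))
      masks[[cls]] <- m & !drop
      masks$soft <- masks$soft | drop
    }
  }
  validate_partition(masks)
  masks
}

#' Convert a tissue mask set to a label volume (0=air 1=lung 2=soft 3=bone)
#' @param masks a `tissue_mask_set`.
#' @return A [cbct_volume] of integer labels (unit HU is nominal; padding 0).
#' @export
masks_to_labels <- function(masks) {
  lab <- array(0, dim = masks$grid$shape)
  lab[masks$lung] <- 1
  lab[masks$soft] <- 2
  lab[masks$bone] <- 3
  vol <- cbct_volume(lab, masks$grid, unit = "HU", padding = 0)
  vol
}

#' Dice similarity coefficient between two binary masks
#' @param a,b logical arrays of identical shape.
#' @return 2|a&b| / (|a|+|b|); 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
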