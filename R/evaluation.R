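#' Intensity histogram of a masked HU image
#'
#' Counts masked voxels per HU bin; values outside the edge range accumulate
#' in the first/last bin, so counts always sum to the number of masked voxels.
#'
#' @param img a [cbct_volume] in HU.
#' @param mask logical array (default: all voxels).
#' @param edges strictly increasing bin edges (default -1100 to 1500 HU in
#'   10 HU bins).
#' @param description free-text label of the mask.
#' @return An object of class `intensity_histogram` with `edges`, `counts`,
#'   `n`, `description`.
#' @export
intensity_histogram <- function(img, mask = NULL,
                                edges = seq(-1100, 1500, by = 10),
                                description = "all voxels") {
  if (img$unit != "HU")
    cbct_stop("cbct_argument_error", "intensity_histogram expects an HU image")
  if (any(diff(edges) <= 0))
    cbct_stop("cbct_argument_error", "bin edges must be strictly increasing")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(img$voxels))
  if (!any(mask))
    cbct_stop("cbct_argument_error", "empty histogram mask")
  v <- img$voxels[mask]
  nb <- length(edges) - 1L
  b <- findInterval(v, edges)
  b[b < 1L] <- 1L
  b[b > nb] <- nb
  structure(list(edges = edges, counts = tabulate(b, nb), n = length(v),
                 description = description),
            class = "intensity_histogram")
}

#' Distance between two intensity histograms
#'
#' Histograms are normalized to frequencies before comparison (the masks may
#' hold different voxel counts). `l1` is the total absolute frequency
#' difference; `chi2` is `0.5 * sum((fa-fb)^2 / (fa+fb))`; `emd` is the 1-D
#' earth mover's distance (area between the CDFs, in HU).
#'
#' @param a,b `intensity_histogram`s with identical bin edges.
#' @param metric `"l1"`, `"chi2"`, or `"emd"`.
#' @return A non-negative scalar; 0 iff the frequency vectors are identical.
#' @export
histogram_distance <- function(a, b, metric = c("l1", "chi2", "emd")) {
  metric <- match.arg(metric)
  if (!isTRUE(all.equal(a$edges, b$edges, tolerance = 0)))
    cbct_stop("cbct_argument_error", "histograms have different bin edges")
  fa <- a$counts / sum(a$counts)
  fb <- b$counts / sum(b$counts)
  switch(metric,
    l1 = sum(abs(fa - fb)),
    chi2 = {
      s <- fa + fb
      nz <- s > 0
      0.5 * sum((fa[nz] - fb[nz])^2 / s[nz])
    },
    emd = {
      widths <- diff(a$edges)
      sum(abs(cumsum(fa - fb)) * widths)
    })
}

#' HU error metrics between a test and a reference volume
#'
#' MAE and RMSE over `body AND fov`, plus the signed mean error inside each
#' ground-truth class mask (restricted to the same region).
#'
#' @param test,reference HU [cbct_volume]s on the same grid.
#' @param masks a `tissue_mask_set` supplying `body`, `fov` and the four class
#'   masks.
#' @return An object of class `hu_error_report`: `mae_hu`, `rmse_hu`,
#'   `class_mean_error_hu` (named), `n_voxels`, `description`.
#' @export
hu_error_metrics <- function(test, reference, masks) {
  check_same_grid(test, reference)
  region <- masks$body & masks$fov
  if (!any(region))
    cbct_stop("cbct_argument_error", "empty evaluation region (body AND fov)")
  d <- test$voxels - reference$voxels
  dr <- d[region]
  cls_err <- vapply(c("air", "lung", "soft", "bone"), function(cls) {
    m <- masks[[cls]] & region
    if (any(m)) mean(d[m]) else NA_real_
  }, numeric(1))
  structure(list(mae_hu = mean(abs(dr)), rmse_hu = sqrt(mean(dr^2)),
                 class_mean_error_hu = cls_err, n_voxels = sum(region),
                 description = "body AND fov"),
            class = "hu_error_report")
}

#' @export
format.hu_error_report <- function(x, ...) {
  sprintf("<hu_error_report MAE %.2f HU, RMSE %.2f HU over %d voxels>",
          x$mae_hu, x$rmse_hu, x$n_voxels)
}

#' @export
print.hu_error_report <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Piecewise-linear HU to relative-electron-density calibration
#'
#' A fixed surrogate curve (not fitted): extrapolation beyond the control
#' points is clamped.
#'
#' @param hu,density control points; density must be non-decreasing with HU.
#' @return An object of class `density_calibration`.
#' @export
density_calibration <- function(hu = c(-1000, -750, 0, 200, 700, 1500),
                                density = c(0.001, 0.25, 1.0, 1.10, 1.43, 1.85)) {
  if (length(hu) != length(density) || length(hu) < 2L)
    cbct_stop("cbct_configuration_error", "need matching HU/density control points")
  if (any(diff(hu) <= 0) || any(diff(density) < 0))
    cbct_stop("cbct_configuration_error",
              "calibration must be strictly increasing in HU and non-decreasing in density")
  structure(list(hu = hu, density = density), class = "density_calibration")
}

#' Convert an HU volume to relative electron density
#' @param img a [cbct_volume] in HU.
#' @param cal a [density_calibration].
#' @return A `DENSITY` [cbct_volume].
#' @export
hu_to_density <- function(img, cal = density_calibration()) {
  if (img$unit != "HU")
    cbct_stop("cbct_argument_error", "hu_to_density expects an HU image")
  v <- approx(cal$hu, cal$density, xout = as.numeric(img$voxels), rule = 2)$y
  cbct_volume(array(v, dim = dim(img$voxels)), img$grid, unit = "DENSITY",
              padding = 0)
}

#' Water-equivalent path length along a ray
#'
#' Trapezoidal line integral of relative electron density from `entry_mm`
#' along `direction` until the ray exits the grid. The integral converges
#' within 0.5% under step halving for smooth volumes.
#'
#' @param density a `DENSITY` [cbct_volume].
#' @param entry_mm world coordinates of the entry point (must lie inside the
#'   grid).
#' @param direction 3-vector (normalized internally).
#' @param step_mm sampling step, at most `min(spacing)/2` (the default).
#' @return WEPL in mm.
#' @export
wepl_along_ray <- function(density, entry_mm, direction,
                           step_mm = min(density$grid$spacing) / 2) {
  if (density$unit != "DENSITY")
    cbct_stop("cbct_argument_error", "wepl_along_ray expects a DENSITY image")
  if (step_mm > min(density$grid$spacing) / 2 + 1e-12)
    cbct_stop("cbct_argument_error", "step_mm must be <= min(spacing)/2")
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) cbct_stop("cbct_argument_error", "direction must be non-zero")
  direction <- direction / nrm
  grid <- density$grid
  idx0 <- world_to_voxel(grid, matrix(entry_mm, 1))
  if (any(idx0 < -1e-9) || any(idx0 > grid$shape - 1 + 1e-9))
    cbct_stop("cbct_argument_error", "entry point lies outside the grid")
  diag_mm <- sqrt(sum((grid$shape * grid$spacing)^2))
  nstep <- ceiling(diag_mm / step_mm) + 2L
  tvals <- (0:nstep) * step_mm
  pts <- cbind(entry_mm[1] + tvals * direction[1],
               entry_mm[2] + tvals * direction[2],
               entry_mm[3] + tvals * direction[3])
  idx <- world_to_voxel(grid, pts)
  s <- cpp_sample_points(as.numeric(density$voxels), grid$shape, idx, 0, FALSE)
  inside <- s$inside
  last <- if (all(inside)) length(inside) else which(!inside)[1] - 1L
  if (last < 2L) return(0)
  v <- s$values[1:last]
  step_mm * (sum(v) - 0.5 * (v[1] + v[last]))
}

#' Per-ray WEPL discrepancy between two volumes
#'
#' Casts a regular 2-D grid of parallel rays (default: anterior-to-posterior,
#' i.e. along +y in LPS, spaced 5 mm in x and z) through both volumes and
#' summarizes the per-ray WEPL differences over rays that intersect the body
#' (reference WEPL at least `min_wepl_mm`).
#'
#' @param test,reference HU [cbct_volume]s on the same grid.
#' @param cal a [density_calibration].
#' @param ray_spacing_mm lateral ray spacing (default 5 mm).
#' @param direction ray direction (default `c(0, 1, 0)`).
#' @param step_mm integration step (default `min(spacing)/2`).
#' @param min_wepl_mm reference-WEPL threshold defining "intersects the body"
#'   (default 10 mm).
#' @return A list of class `wepl_report`: `mean_abs_mm`, `max_abs_mm`,
#'   `n_rays`, and a `rays` data frame (x, z, wepl_test, wepl_ref, delta).
#' @export
wepl_discrepancy_map <- function(test, reference, cal = density_calibration(),
                                 ray_spacing_mm = 5, direction = c(0, 1, 0),
                                 step_mm = NULL, min_wepl_mm = 10) {
  check_same_grid(test, reference)
  grid <- test$grid
  if (is.null(step_mm)) step_mm <- min(grid$spacing) / 2
  dt <- hu_to_density(test, cal)
  dr <- hu_to_density(reference, cal)
  lo <- voxel_to_world(grid, matrix(c(0, 0, 0), 1))[1, ]
  hi <- voxel_to_world(grid, matrix(grid$shape - 1, 1))[1, ]
  xs <- seq(lo[1], hi[1], by = ray_spacing_mm)
  zs <- seq(lo[3], hi[3], by = ray_spacing_mm)
  rays <- expand.grid(x = xs, z = zs)
  wt <- numeric(nrow(rays)); wr <- numeric(nrow(rays))
  for (r in seq_len(nrow(rays))) {
    entry <- c(rays$x[r], lo[2], rays$z[r])
    wt[r] <- wepl_along_ray(dt, entry, direction, step_mm)
    wr[r] <- wepl_along_ray(dr, entry, direction, step_mm)
  }
  keep <- wr >= min_wepl_mm
  if (!any(keep))
    cbct_stop("cbct_argument_error", "no ray intersects the body")
  delta <- wt[keep] - wr[keep]
  structure(list(mean_abs_mm = mean(abs(delta)), max_abs_mm = max(abs(delta)),
                 n_rays = sum(keep),
                 rays = data.frame(x = rays$x[keep], z = rays$z[keep],
                                   wepl_test = wt[keep], wepl_ref = wr[keep],
                                   delta = delta)),
            class = "wepl_report")
}

#' @export
format.wepl_report <- function(x, ...) {
  sprintf("<wepl_report mean|d|=%.2f mm, max|d|=%.2f mm over %d rays>",
          x$mean_abs_mm, x$max_abs_mm, x$n_rays)
}

#' @export
print.wepl_report <- function(x, ...) { cat(format(x), "\n"); invisible(x) }
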