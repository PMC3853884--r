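#' Rigid registration settings
#'
#' @param metric `"mutual_information"` (default; robust to the CBCT's HU
#'   bias) or `"mean_squared_error"`.
#' @param pyramid_levels number of resolution levels (default 3; sample
#'   strides 4/2/1 from coarse to fine).
#' @param max_iterations_per_level optimizer iteration cap per level
#'   (default 150).
#' @param sampling_fraction fraction of candidate fixed-image voxels used for
#'   the metric at the finest level, in (0, 1] (default 0.02; at least 2000
#'   voxels are always used).
#' @param seed RNG seed for voxel sampling (determinism contract).
#' @param translation_only optimize translation only (3 DOF).
#' @return An object of class `registration_settings`.
#' @export
registration_settings <- function(metric = c("mutual_information",
                                             "mean_squared_error"),
                                  pyramid_levels = 3L,
                                  max_iterations_per_level = 150L,
                                  sampling_fraction = 0.02,
                                  seed = 0L, translation_only = FALSE) {
  metric <- match.arg(metric)
  if (pyramid_levels < 1L)
    cbct_stop("cbct_argument_error", "pyramid_levels must be >= 1")
  if (!(sampling_fraction > 0 && sampling_fraction <= 1))
    cbct_stop("cbct_argument_error", "sampling_fraction must be in (0, 1]")
  structure(list(metric = metric, pyramid_levels = as.integer(pyramid_levels),
                 max_iterations_per_level = as.integer(max_iterations_per_level),
                 sampling_fraction = sampling_fraction, seed = as.integer(seed),
                 translation_only = isTRUE(translation_only)),
            class = "registration_settings")
}

# world center of mass of a mask
mask_center_of_mass <- function(mask, grid) {
  idx <- which(mask)
  if (!length(idx)) return(voxel_to_world(grid, matrix((grid$shape - 1) / 2, 1))[1, ])
  dims <- grid$shape
  i <- (idx - 1) %% dims[1]
  j <- ((idx - 1) %/% dims[1]) %% dims[2]
  k <- (idx - 1) %/% (dims[1] * dims[2])
  colMeans(voxel_to_world(grid, cbind(i, j, k)))
}

# Negative mutual information (nats) of two aligned sample vectors. The
# moving values are linearly binned (partial-volume weighting between the two
# adjacent bins), which makes the objective smooth in the transform
# parameters and suppresses grid-aliasing local optima.
neg_mutual_information <- function(fb, mvals, mlo, mbw, nbins) {
  pos <- (mvals - mlo) / mbw + 0.5
  b0 <- floor(pos)
  w1 <- pos - b0
  b0 <- pmin(pmax(b0, 1), nbins)
  b1 <- pmin(b0 + 1, nbins)
  idx <- c(fb + nbins * (b0 - 1), fb + nbins * (b1 - 1))
  w <- c(1 - w1, w1)
  acc <- rowsum(w, idx)
  joint <- numeric(nbins * nbins)
  joint[as.integer(rownames(acc))] <- acc
  n <- sum(joint)
  p <- joint / n
  px <- rowSums(matrix(p, nbins, nbins))
  py <- colSums(matrix(p, nbins, nbins))
  nz <- p > 0
  outer_p <- as.numeric(outer(px, py))
  -sum(p[nz] * log(p[nz] / outer_p[nz]))
}

#' Rigid registration of a CBCT to a planning CT
#'
#' Estimates the 6-DOF (or 3-DOF) rigid transform mapping the moving image's
#' world coordinates into the fixed image's, by maximizing mutual information
#' (or minimizing mean squared error) over seeded random samples of the fixed
#' body region, with a coarse-to-fine sampling pyramid and Nelder-Mead
#' optimization. Initialization aligns the body-mask centers of mass, which is
#' robust to field-of-view truncation. Deterministic given `settings$seed`.
#'
#' @param fixed,moving HU [cbct_volume]s (planning CT and CBCT).
#' @param settings a [registration_settings].
#' @return A list of class `cbct_registration`: `transform` (the
#'   [rigid_transform]), `metric` (final metric value: mutual information in
#'   nats, or MSE), `initial_metric`, and `settings`.
#' @export
register_rigid <- function(fixed, moving, settings = registration_settings()) {
  if (fixed$unit != "HU" || moving$unit != "HU")
    cbct_stop("cbct_argument_error", "registration expects HU images")
  body_f <- tryCatch(compute_body_mask(fixed), error = function(e) fixed$voxels > -500)
  body_m <- tryCatch(compute_body_mask(moving), error = function(e) moving$voxels > -500)
  com_f <- mask_center_of_mass(body_f, fixed$grid)
  com_m <- mask_center_of_mass(body_m, moving$grid)
  center <- com_f
  par0 <- if (settings$translation_only) com_f - com_m
          else c(0, 0, 0, com_f - com_m)
  par_to_transform <- function(par) {
    if (settings$translation_only) rigid_transform(c(0, 0, 0), par, center)
    else rigid_transform(par[1:3], par[4:6], center)
  }
  # candidate fixed voxels: body plus a small shell (surface gradients help)
  cand_mask <- dilate3d(body_f, 2)
  cand <- which(cand_mask)
  dims <- fixed$grid$shape
  nbins <- 32L
  frng <- range(fixed$voxels[cand])
  fbreaks <- seq(frng[1], frng[2] + 1e-6, length.out = nbins + 1L)
  mrng <- range(moving$voxels)
  mlo <- mrng[1] - 1e-6
  mbw <- (mrng[2] + 1e-6 - mlo) / nbins
  Am <- grid_affine(moving$grid)
  make_objective <- function(pts_world, fvals) {
    fb <- findInterval(fvals, fbreaks, all.inside = TRUE)
    function(par) {
      tr <- par_to_transform(par)
      Minv <- transform_matrix(invert_transform(tr))
      q <- t(Minv[1:3, 1:3] %*% t(pts_world) + Minv[1:3, 4])
      idx <- t(solve(Am, t(q) - moving$grid$origin))
      s <- cpp_sample_points(as.numeric(moving$voxels), moving$grid$shape,
                             idx, moving$padding, FALSE)
      ins <- s$inside
      if (mean(ins) < 0.2) return(1e6)
      if (settings$metric == "mutual_information") {
        neg_mutual_information(fb[ins], s$values[ins], mlo, mbw, nbins)
      } else {
        mean((fvals[ins] - s$values[ins])^2)
      }
    }
  }
  strides <- rev(c(1L, 2L, 4L, 8L)[seq_len(settings$pyramid_levels)])
  par <- par0
  obj_final <- NULL
  for (lev in seq_along(strides)) {
    s <- strides[lev]
    i <- (cand - 1) %% dims[1]
    j <- ((cand - 1) %/% dims[1]) %% dims[2]
    k <- (cand - 1) %/% (dims[1] * dims[2])
    keep <- (i %% s == 0L) & (j %% s == 0L) & (k %% s == 0L)
    sub <- cand[keep]
    n_target <- max(2000L, ceiling(settings$sampling_fraction * length(sub)))
    if (length(sub) > n_target) {
      sub <- with_seed(settings$seed + lev,
                       sub[sample.int(length(sub), n_target)])
    }
    pts <- voxel_to_world(fixed$grid,
                          cbind((sub - 1) %% dims[1],
                                ((sub - 1) %/% dims[1]) %% dims[2],
                                (sub - 1) %/% (dims[1] * dims[2])))
    obj <- make_objective(pts, fixed$voxels[sub])
    # quasi-Newton step with coarse numeric gradients (rides the smooth
    # linearly-binned metric), then a Nelder-Mead polish; keep the best
    fit_b <- optim(par, obj, method = "BFGS",
                   control = list(maxit = min(60L,
                                              settings$max_iterations_per_level),
                                  ndeps = rep(0.02, length(par)),
                                  reltol = 1e-10))
    fit_n <- optim(fit_b$par, obj, method = "Nelder-Mead",
                   control = list(maxit = settings$max_iterations_per_level,
                                  reltol = 1e-9))
    cands <- list(list(par = par, value = obj(par)), fit_b, fit_n)
    par <- cands[[which.min(vapply(cands, `[[`, numeric(1), "value"))]]$par
    obj_final <- obj
  }
  init_val <- obj_final(par0)
  final_val <- obj_final(par)
  if (final_val > init_val + 1e-12) {
    cond <- structure(class = c("cbct_convergence_error", "cbctcorr_error",
                                "error", "condition"),
                      list(message = "registration metric worsened; best-so-far transform attached",
                           call = sys.call(-1),
                           transform = par_to_transform(par0),
                           metric = init_val))
    stop(cond)
  }
  metric_out <- if (settings$metric == "mutual_information") -final_val else final_val
  metric_init <- if (settings$metric == "mutual_information") -init_val else init_val
  structure(list(transform = par_to_transform(par), metric = metric_out,
                 initial_metric = metric_init, settings = settings),
            class = "cbct_registration")
}

#' @export
format.cbct_registration <- function(x, ...) {
  sprintf("<cbct_registration %s metric=%.5g\n  %s>",
          x$settings$metric, x$metric, format(x$transform))
}

#' @export
print.cbct_registration <- function(x, ...) { cat(format(x), "\n"); invisible(x) }
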