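#' Rigid (6-DOF) world-space transform
#'
#' Maps moving-image (CBCT) world coordinates into fixed-image (planning CT)
#' world coordinates as `p' = R (p - c) + c + t`, where `R` is the rotation
#' built from Euler angles applied in fixed Z-Y-X order
#' (`R = Rz(az) %*% Ry(ay) %*% Rx(ax)`), `c` the rotation center and `t` the
#' translation, all in mm / degrees.
#'
#' @param rotation_deg Euler angles (degrees) about x, y, z, applied Z-Y-X.
#' @param translation_mm translation vector (mm).
#' @param center_mm rotation center in world coordinates (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0),
                            center_mm = c(0, 0, 0)) {
  rotation_deg <- as.numeric(rotation_deg)
  translation_mm <- as.numeric(translation_mm)
  center_mm <- as.numeric(center_mm)
  stopifnot(length(rotation_deg) == 3, length(translation_mm) == 3,
            length(center_mm) == 3)
  structure(list(rotation_deg = rotation_deg,
                 translation_mm = translation_mm,
                 center_mm = center_mm),
            class = "rigid_transform")
}

#' @export
format.rigid_transform <- function(x, ...) {
  sprintf("<rigid_transform rot=(%s) deg, t=(%s) mm, c=(%s) mm>",
          paste(signif(x$rotation_deg, 5), collapse = ", "),
          paste(signif(x$translation_mm, 5), collapse = ", "),
          paste(signif(x$center_mm, 5), collapse = ", "))
}

#' @export
print.rigid_transform <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

rotation_matrix <- function(rotation_deg) {
  a <- rotation_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# Euler Z-Y-X angles (degrees) from a rotation matrix
euler_from_matrix <- function(R) {
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  ay <- asin(sy)
  if (abs(sy) < 1 - 1e-9) {
    ax <- atan2(R[3, 2], R[3, 3])
    az <- atan2(R[2, 1], R[1, 1])
  } else {
    # gimbal lock: put all z-x mixing into x
    ax <- atan2(-R[2, 3], R[2, 2])
    az <- 0
  }
  c(ax, ay, az) * 180 / pi
}

# 4x4 homogeneous matrix of the transform
transform_matrix <- function(t) {
  R <- rotation_matrix(t$rotation_deg)
  d <- t$center_mm + t$translation_mm - R %*% t$center_mm
  rbind(cbind(R, d), c(0, 0, 0, 1))
}

#' Apply a rigid transform to world points
#' @param t a [rigid_transform].
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of mapped coordinates.
#' @export
transform_points <- function(t, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  M <- transform_matrix(t)
  t(M[1:3, 1:3] %*% t(pts) + M[1:3, 4])
}

#' Invert a rigid transform
#' @param t a [rigid_transform].
#' @return The inverse `rigid_transform` (same rotation center).
#' @export
invert_transform <- function(t) {
  M <- transform_matrix(t)
  Rinv <- t(M[1:3, 1:3])
  dinv <- -Rinv %*% M[1:3, 4]
  # express with the same center: t2 = dinv + (Rinv - I) c ... solve directly
  c0 <- t$center_mm
  t2 <- as.numeric(dinv + Rinv %*% c0 - c0)
  rigid_transform(euler_from_matrix(Rinv), t2, c0)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` maps `p` to `a(b(p))`.
#' @param a,b [rigid_transform] objects.
#' @return The composed `rigid_transform` (center at the origin).
#' @export
compose_transforms <- function(a, b) {
  M <- transform_matrix(a) %*% transform_matrix(b)
  rigid_transform(euler_from_matrix(M[1:3, 1:3]), as.numeric(M[1:3, 4]), c(0, 0, 0))
}

#' Write a rigid transform as a plain-text key-value file
#'
#' Three lines (`rotation_deg`, `translation_mm`, `center_mm`), each followed
#' by three full-precision numbers; the format used by the `register` CLI and
#' accepted wherever a clinical registration can be supplied.
#' @param t a [rigid_transform].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(t, path) {
  fmt <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  lines <- c(paste("rotation_deg:", fmt(t$rotation_deg)),
             paste("translation_mm:", fmt(t$translation_mm)),
             paste("center_mm:", fmt(t$center_mm)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a rigid transform from a plain-text key-value file
#' @param path file written by [write_transform()] (or by hand; missing keys
#'   default to zero, so pure-translation clinical records are accepted).
#' @return A [rigid_transform].
#' @export
read_transform <- function(path) {
  if (!file.exists(path))
    cbct_stop("cbct_io_error", paste("transform file not found:", path))
  lines <- readLines(path, warn = FALSE)
  vals <- list(rotation_deg = c(0, 0, 0), translation_mm = c(0, 0, 0),
               center_mm = c(0, 0, 0))
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" || startsWith(ln, "#")) next
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    if (!key %in% names(vals))
      cbct_stop("cbct_format_error", paste("unknown transform key:", key))
    v <- as.numeric(strsplit(trimws(paste(kv[-1], collapse = ":")), "[ ,]+")[[1]])
    if (length(v) != 3 || any(!is.finite(v)))
      cbct_stop("cbct_format_error", paste("malformed transform values for", key))
    vals[[key]] <- v
  }
  rigid_transform(vals$rotation_deg, vals$translation_mm, vals$center_mm)
}
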