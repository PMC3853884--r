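file_format <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii$", p) || grepl("\\.nii\\.gz$", p)) return("nifti")
  if (grepl("\\.mha$", p) || grepl("\\.mhd$", p)) return("metaimage")
  cbct_stop("cbct_format_error",
            paste("unsupported volume format (expect .nii/.nii.gz/.mha/.mhd):", path))
}

sidecar_path <- function(path) paste0(path, ".meta.json")

# NIfTI stores RAS world axes; internally we use LPS. Flip x and y.
LPS_FLIP <- diag(c(-1, -1, 1))

#' Read a volumetric image (NIfTI or MetaImage)
#'
#' Voxel values and grid geometry (spacing, origin, direction cosines) are
#' taken from the file header; world coordinates are converted to the LPS
#' millimetre convention used throughout the package. The intensity unit and
#' padding value are recovered from a `<path>.meta.json` sidecar (NIfTI) or
#' from header fields (MetaImage) when present, and default to HU / -1000.
#'
#' @param path a `.nii`, `.nii.gz`, `.mha`, or `.mhd` file.
#' @return A [cbct_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    cbct_stop("cbct_io_error", paste("file not found:", path))
  fmt <- file_format(path)
  if (fmt == "nifti") vol <- read_nifti_volume(path) else vol <- read_metaimage(path)
  sc <- sidecar_path(path)
  if (fmt == "nifti" && file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$intensity_unit))
      vol <- cbct_volume(vol$voxels, vol$grid, unit = meta$intensity_unit,
                         padding = if (is.null(meta$padding_value))
                           default_padding(meta$intensity_unit) else meta$padding_value)
  }
  vol
}

#' Write a volumetric image (NIfTI or MetaImage)
#'
#' Voxels are stored as 64-bit floats so that a write/read round trip is
#' lossless. For NIfTI the intensity unit and padding value are recorded in a
#' `<path>.meta.json` sidecar; MetaImage carries them in header fields.
#'
#' @param img a [cbct_volume].
#' @param path output path ending in `.nii`, `.nii.gz`, `.mha`, or `.mhd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path) {
  if (!inherits(img, "cbct_volume"))
    cbct_stop("cbct_argument_error", "img must be a cbct_volume")
  dir <- dirname(path)
  if (!dir.exists(dir))
    cbct_stop("cbct_io_error", paste("parent directory does not exist:", dir))
  fmt <- file_format(path)
  if (fmt == "nifti") {
    write_nifti_volume(img, path)
    jsonlite::write_json(list(intensity_unit = img$unit,
                              padding_value = img$padding),
                         sidecar_path(path), auto_unbox = TRUE, digits = NA)
  } else {
    write_metaimage(img, path)
  }
  invisible(path)
}

read_nifti_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) cbct_stop("cbct_format_error",
                    paste0("cannot read NIfTI file ", path, ": ", conditionMessage(e))))
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    cbct_stop("cbct_format_error",
              paste0(path, " is not a 3-D image (", length(dim(arr)), " dims)"))
  aff <- RNifti::xform(img)             # RAS voxel->world, 0-based indices
  A_lps <- LPS_FLIP %*% aff[1:3, 1:3]
  origin <- as.numeric(LPS_FLIP %*% aff[1:3, 4])
  spacing <- sqrt(colSums(A_lps^2))
  direction <- sweep(A_lps, 2, spacing, "/")
  grid <- image_grid(dim(arr), spacing, origin, direction)
  cbct_volume(array(as.numeric(arr), dim = dim(arr)), grid)
}

write_nifti_volume <- function(img, path) {
  A_lps <- grid_affine(img$grid)
  aff <- rbind(cbind(LPS_FLIP %*% A_lps, as.numeric(LPS_FLIP %*% img$grid$origin)),
               c(0, 0, 0, 1))
  nim <- RNifti::asNifti(img$voxels, datatype = "double",
                         pixdim = img$grid$spacing)
  nim <- RNifti::`sform<-`(nim, structure(aff, code = 2L))
  RNifti::writeNifti(nim, path)
}

# ---- MetaImage (.mha local / .mhd + .raw), uncompressed ---------------------

MET_TYPES <- list(
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE)
)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      cbct_stop("cbct_format_error", paste("truncated MetaImage header:", path))
    kv <- regmatches(line, regexpr("=", line), invert = TRUE)[[1]]
    if (length(kv) != 2L)
      cbct_stop("cbct_format_error", paste("malformed MetaImage header line:", line))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["NDims"]], "3"))
    cbct_stop("cbct_format_error", paste0(path, " is not a 3-D image (NDims=",
                                          hdr[["NDims"]], ")"))
  if (identical(hdr[["CompressedData"]], "True"))
    cbct_stop("cbct_format_error", paste("compressed MetaImage not supported:", path))
  num <- function(key, default = NULL) {
    if (is.null(hdr[[key]])) return(default)
    as.numeric(strsplit(trimws(hdr[[key]]), "[ \t]+")[[1]])
  }
  shape <- as.integer(num("DimSize"))
  spacing <- num("ElementSpacing", c(1, 1, 1))
  origin <- num("Offset", c(0, 0, 0))
  tm <- num("TransformMatrix", c(1, 0, 0, 0, 1, 0, 0, 0, 1))
  direction <- t(matrix(tm, 3, 3))      # header lists rows of the matrix
  et <- hdr[["ElementType"]]
  spec <- MET_TYPES[[et]]
  if (is.null(spec))
    cbct_stop("cbct_format_error", paste("unsupported MetaImage ElementType:", et))
  endian <- if (identical(hdr[["BinaryDataByteOrderMSB"]], "True")) "big" else "little"
  n <- prod(shape)
  datafile <- hdr[["ElementDataFile"]]
  if (identical(datafile, "LOCAL")) {
    raw_vals <- readBin(con, spec$what, n = n, size = spec$size,
                        signed = spec$signed, endian = endian)
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath))
      cbct_stop("cbct_io_error", paste("MetaImage data file not found:", rawpath))
    rcon <- file(rawpath, "rb")
    on.exit(close(rcon), add = TRUE)
    raw_vals <- readBin(rcon, spec$what, n = n, size = spec$size,
                        signed = spec$signed, endian = endian)
  }
  if (length(raw_vals) != n)
    cbct_stop("cbct_format_error", paste("MetaImage voxel data truncated:", path))
  unit <- hdr[["IntensityUnit"]]
  if (is.null(unit) || !unit %in% VOLUME_UNITS) unit <- "HU"
  padding <- if (is.null(hdr[["PaddingValue"]])) default_padding(unit)
             else as.numeric(hdr[["PaddingValue"]])
  grid <- image_grid(shape, spacing, origin, direction)
  cbct_volume(array(as.numeric(raw_vals), dim = shape), grid,
              unit = unit, padding = padding)
}

write_metaimage <- function(img, path) {
  local_data <- grepl("\\.mha$", tolower(path))
  datafile <- if (local_data) "LOCAL"
              else paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  fmt <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           paste("TransformMatrix =", fmt(as.numeric(t(img$grid$direction)))),
           paste("Offset =", fmt(img$grid$origin)),
           paste("ElementSpacing =", fmt(img$grid$spacing)),
           paste("DimSize =", paste(img$grid$shape, collapse = " ")),
           "ElementType = MET_DOUBLE",
           paste("IntensityUnit =", img$unit),
           paste("PaddingValue =", sprintf("%.17g", img$padding)),
           paste("ElementDataFile =", datafile))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (local_data) {
    writeBin(as.numeric(img$voxels), con, size = 8L, endian = "little")
  } else {
    rcon <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(as.numeric(img$voxels), rcon, size = 8L, endian = "little")
  }
  invisible(path)
}

# ---- resampling -------------------------------------------------------------

#' Resample a volume onto a reference grid through a rigid transform
#'
#' Each reference voxel center `p` (fixed/world space) is pulled back to the
#' moving image at `transform^{-1}(p)` and interpolated there. Samples falling
#' outside the moving image's support are set to `moving$padding` and flagged
#' `FALSE` in the returned `support` array (stored on the result).
#'
#' @param moving a [cbct_volume] to resample.
#' @param reference an [image_grid] (or a `cbct_volume`, whose grid is used).
#' @param transform a [rigid_transform] mapping moving world coordinates into
#'   reference world coordinates; identity by default.
#' @param interpolation `"linear"` (default) or `"nearest"`; use nearest for
#'   masks and label images.
#' @return A `cbct_volume` on `reference` with a logical `support` field.
#' @export
resample_to_grid <- function(moving, reference, transform = rigid_transform(),
                             interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (inherits(reference, "cbct_volume")) reference <- reference$grid
  if (!inherits(reference, "image_grid"))
    cbct_stop("cbct_argument_error", "reference must be an image_grid or cbct_volume")
  if (any(reference$shape < 1L))
    cbct_stop("cbct_argument_error", "degenerate reference grid")
  # continuous moving index of reference voxel i:
  #   j = Am^-1 (Tinv(Ar i + or) - om) = M i + b
  Ar <- grid_affine(reference)
  Am <- grid_affine(moving$grid)
  Minv <- transform_matrix(invert_transform(transform))
  Rinv <- Minv[1:3, 1:3]; dinv <- Minv[1:3, 4]
  M <- solve(Am, Rinv %*% Ar)
  b <- as.numeric(solve(Am, Rinv %*% reference$origin + dinv - moving$grid$origin))
  res <- cpp_affine_sample(as.numeric(moving$voxels), moving$grid$shape,
                           M, b, reference$shape, moving$padding,
                           interpolation == "nearest")
  out <- cbct_volume(array(res$values, dim = reference$shape), reference,
                     unit = moving$unit, padding = moving$padding)
  out$support <- array(res$support, dim = reference$shape)
  out
}
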