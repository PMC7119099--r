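#' @importFrom stats coef lm mad median optim predict qt quantile rnorm runif sd
#'   setNames vcov aov TukeyHSD pf pt var complete.cases model.matrix as.formula
#' @importFrom utils head tail
NULL

# Array axis convention used throughout: data[slice, row, col], with
# spacing = c(dx, dy, dz) where dx/dy are the in-plane (col/row) steps and
# dz the slice thickness.  Physical coordinates of voxel (s, r, c)
# (0-based) are origin + c(c*dx, r*dy, s*dz).

#' Create a 3-D volume image
#'
#' A `volume_image` is the carrier for all scalar volumes handled by the
#' pipeline: T1-weighted intensities, Dixon water/fat pairs, estimated bias
#' fields and fat-fraction maps. The array is indexed `[slice, row, col]`;
#' `spacing` holds the physical voxel steps `(dx, dy, dz)` in mm where
#' `dx`/`dy` are in-plane and `dz` is the slice thickness.
#'
#' @param data 3-D numeric array indexed `[slice, row, col]`.
#' @param spacing numeric length-3, voxel spacing `(dx, dy, dz)` in mm, all
#'   strictly positive.
#' @param origin numeric length-3, physical position (mm) of the first voxel
#'   centre.
#' @return An object of class `volume_image` with elements `data`, `spacing`
#'   and `origin`.
#' @examples
#' img <- volume_image(array(0, dim = c(4, 8, 8)), spacing = c(0.5, 0.5, 3.0))
#' voxel_volume(img)
#' @export
volume_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  if (any(dim(data) < 1L))
    stop("all image dimensions must be positive", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  if (any(!is.finite(data)))
    stop("image values must all be finite", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_image> %d slices x %d rows x %d cols, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g], origin (%g, %g, %g) mm\n",
              min(x$data), max(x$data), x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Create a binary mask on the grid of a reference image
#'
#' Masks represent the per-slice hand cross-sectional area and the muscle
#' volume of interest (VOI). A mask always carries the spacing/origin of the
#' image it was derived from, and operations that combine a mask with an
#' image check grid equality first.
#'
#' @param data 3-D array of 0/1 (logical or numeric) indexed `[slice, row, col]`.
#' @param reference a `volume_image` supplying the grid, or `NULL` to pass
#'   `spacing`/`origin` directly.
#' @param spacing,origin grid geometry, used when `reference` is `NULL`.
#' @return Object of class `binary_mask` with integer 0/1 `data`.
#' @export
binary_mask <- function(data, reference = NULL, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask `data` must be a 3-D array", call. = FALSE)
  v <- as.integer(data)
  if (any(is.na(v)) || !all(v %in% c(0L, 1L)))
    stop("mask values must be 0 or 1", call. = FALSE)
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "volume_image"))
    if (!identical(dim(data), dim(reference$data)))
      stop("mask shape does not match reference image", call. = FALSE)
    spacing <- reference$spacing
    origin <- reference$origin
  }
  structure(list(data = array(v, dim = dim(data)),
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask> %d x %d x %d, %d foreground voxels\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

#' Analysis bounds along the slice axis
#'
#' The study's output parameters are computed between the proximal and distal
#' ends of the third metacarpal bone, marked as two slice indices. Indices
#' are 0-based and the interval is inclusive on both ends.
#'
#' @param proximal_slice,distal_slice 0-based slice indices,
#'   `0 <= proximal_slice <= distal_slice`.
#' @return Object of class `analysis_bounds`.
#' @export
analysis_bounds <- function(proximal_slice, distal_slice) {
  p <- as.integer(proximal_slice); d <- as.integer(distal_slice)
  if (length(p) != 1L || length(d) != 1L || is.na(p) || is.na(d))
    stop("bounds must be single integers", call. = FALSE)
  if (p < 0L || p > d)
    stop("require 0 <= proximal_slice <= distal_slice", call. = FALSE)
  structure(list(proximal_slice = p, distal_slice = d),
            class = "analysis_bounds")
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

check_same_grid <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    stop(sprintf("%s are not on the same grid (shape/spacing/origin mismatch)",
                 what), call. = FALSE)
  invisible(TRUE)
}

#' Physical volume of a single voxel
#'
#' Total segmented volumes are accumulated as voxel counts times this factor.
#'
#' @param img a `volume_image` or `binary_mask`.
#' @return Voxel volume dx*dy*dz in mm^3.
#' @examples
#' voxel_volume(volume_image(array(0, c(2, 2, 2)), spacing = c(0.5, 0.5, 3)))
#' @export
voxel_volume <- function(img) {
  prod(img$spacing)
}

#' Read a NIfTI-1 volume
#'
#' Loads a 3-D scalar volume; voxel spacing is taken from the file's pixdim
#' and the origin from its sform/qform offset. The array is returned in the
#' package's `[slice, row, col]` order.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [volume_image].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  nii <- RNifti::readNifti(path)
  d <- dim(nii)
  if (length(d) == 4L && d[4] == 1L) {
    nii2 <- array(as.numeric(nii), dim = d[1:3])
  } else if (length(d) == 3L) {
    nii2 <- array(as.numeric(nii), dim = d)
  } else {
    stop(sprintf("expected a 3-D image, got %d dimensions in %s",
                 length(d), path), call. = FALSE)
  }
  pd <- RNifti::pixdim(nii)[1:3]
  if (any(!is.finite(pd)) || any(pd <= 0))
    stop(sprintf("non-positive voxel spacing in %s", path), call. = FALSE)
  xf <- try(RNifti::xform(nii), silent = TRUE)
  orig <- c(0, 0, 0)
  if (!inherits(xf, "try-error") && is.matrix(xf)) orig <- xf[1:3, 4]
  # NIfTI stores [x(col), y(row), z(slice)] fastest-first; permute to
  # [slice, row, col]
  volume_image(aperm(nii2, c(3, 2, 1)), spacing = pd, origin = orig)
}

#' Write a volume or mask as NIfTI-1
#'
#' Images are written as 32-bit float, masks as 8-bit unsigned integer.
#' Spacing and origin go into pixdim and the sform (code 2).
#'
#' @param img a [volume_image] or [binary_mask].
#' @param path output path (`.nii` or `.nii.gz`); parent must be writable.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(img, path) {
  stopifnot(inherits(img, "volume_image") || inherits(img, "binary_mask"))
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0)
    stop(sprintf("cannot write to directory: %s", dir), call. = FALSE)
  arr <- aperm(img$data, c(3, 2, 1))  # back to [x, y, z]
  dtype <- if (inherits(img, "binary_mask")) "uint8" else "float"
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- img$spacing
  m <- diag(4)
  m[1, 1] <- img$spacing[1]; m[2, 2] <- img$spacing[2]; m[3, 3] <- img$spacing[3]
  m[1:3, 4] <- img$origin
  nii <- RNifti::`sform<-`(nii, structure(m, code = 2L))
  RNifti::writeNifti(nii, path, datatype = dtype)
  invisible(path)
}

#' Read a NIfTI-1 mask
#'
#' @param path path to a mask written by [write_volume].
#' @return A [binary_mask].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  binary_mask(array(as.integer(v$data != 0), dim = dim(v$data)),
              spacing = v$spacing, origin = v$origin)
}

# physical coordinates (mm) of every voxel centre, rows = voxels in array
# order, columns = (x, y, z); 0-based indices
voxel_coords <- function(img) {
  d <- dim(img$data)
  s <- img$spacing; o <- img$origin
  idx <- arrayInd(seq_len(prod(d)), d)  # [slice, row, col], 1-based
  cbind(x = o[1] + (idx[, 3] - 1) * s[1],
        y = o[2] + (idx[, 2] - 1) * s[2],
        z = o[3] + (idx[, 1] - 1) * s[3])
}
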