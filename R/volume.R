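#' Voxelized scalar volume
#'
#' The shared 3D container for CT-like images (HU) and dose grids (Gy).
#' Axes follow the common DICOM patient convention: x towards patient left,
#' y towards posterior, z towards superior, all in mm. `origin_mm` is the
#' world position of the centre of voxel `[1, 1, 1]`.
#'
#' @param values 3D numeric array, finite values only.
#' @param spacing_mm Positive length-3 voxel size in mm.
#' @param origin_mm Length-3 world coordinate of the first voxel centre.
#' @param unit One of `"HU"`, `"Gy"`, `"unitless"`.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing_mm = c(1, 1, 1),
                         origin_mm = c(0, 0, 0),
                         unit = c("HU", "Gy", "unitless")) {
  unit <- match.arg(unit)
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  if (!all(is.finite(values))) stop("`values` must be finite")
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive numbers")
  if (length(origin_mm) != 3L) stop("`origin_mm` must have length 3")
  structure(list(values = values, spacing_mm = spacing_mm,
                 origin_mm = origin_mm, unit = unit),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> %s, %s voxels @ %s mm, origin (%s) mm\n",
              x$unit, paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"),
              paste(format(x$origin_mm), collapse = ", ")))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$values)

#' Volume of one voxel in cc
#' @param volume A [voxel_volume()].
#' @return Scalar, cm^3.
#' @export
voxel_cc <- function(volume) prod(volume$spacing_mm) / 1000

#' World coordinates of voxel centres along each axis
#' @param volume A [voxel_volume()].
#' @return List of three numeric vectors (x, y, z positions in mm).
#' @export
axis_coords <- function(volume) {
  d <- dim(volume$values)
  lapply(1:3, function(a)
    volume$origin_mm[a] + (seq_len(d[a]) - 1) * volume$spacing_mm[a])
}

#' Voxel-centre world coordinates for a mask
#'
#' @param volume Reference [voxel_volume()].
#' @param mask Logical array on the same grid.
#' @return n x 3 matrix of mm coordinates.
#' @export
mask_coords <- function(volume, mask) {
  stopifnot(identical(dim(mask), dim(volume$values)))
  idx <- which(mask, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, volume$spacing_mm, `*`), 2, volume$origin_mm, `+`)
}

#' Centroid of a binary mask (unweighted mean of voxel centres)
#' @inheritParams mask_coords
#' @return Length-3 mm coordinate.
#' @export
mask_centroid <- function(volume, mask) {
  xyz <- mask_coords(volume, mask)
  if (nrow(xyz) == 0L) stop("mask is empty")
  colMeans(xyz)
}

#' Structure volume by voxel counting
#' @inheritParams mask_coords
#' @return Volume in cc.
#' @export
mask_volume_cc <- function(volume, mask) sum(mask) * voxel_cc(volume)

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing_mm - b$spacing_mm) < tol) &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}
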