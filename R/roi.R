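#' Segment bone by global gray thresholding
#'
#' A voxel is classified as bone iff `lo <= gray <= hi` (both bounds
#' inclusive, so the conventional 70..255 window includes the 8-bit maximum).
#'
#' @param stack a [gray_stack()] or an integer array of gray values.
#' @param lo,hi gray-level threshold window (defaults 70 and 255).
#' @return logical array, TRUE = bone.
#' @export
segment_bone <- function(stack, lo = 70, hi = 255) {
  if (lo > hi) stop("invalid threshold: lo > hi")
  if (lo < 0 || hi > 255) stop("thresholds must lie in [0, 255]")
  v <- if (inherits(stack, "gray_stack")) stack$voxels else stack
  v >= lo & v <= hi
}

#' Extract a cylindrical trabecular region of interest
#'
#' Restricts a segmented bone mask (or a density stack) to a cylinder aligned
#' with the slice axis. In-plane membership is decided by the voxel-center
#' test: a voxel belongs to the cylinder iff its center lies within
#' `diameter_mm / 2` of the cylinder axis. The slice range is half-open:
#' slices `z_start + 1` .. `z_end` (0-based offsets, so the ROI height is
#' `(z_end - z_start) * voxel_size`).
#'
#' @param x logical bone mask (3D array), [gray_stack()] or [density_stack()].
#' @param voxel_size_mm voxel size; required when `x` is a bare array.
#' @param center_xy cylinder axis position `c(row, col)` in voxel units
#'   (defaults to the in-plane center of the grid).
#' @param diameter_mm cylinder diameter in mm (defaults to the largest
#'   inscribed circle).
#' @param z_start,z_end slice offsets, `0 <= z_start < z_end <= n_slices`
#'   (defaults: full stack).
#' @return For a mask: object of class `trab_roi` with fields `mask` (bone
#'   within the cylinder), `region` (cylinder membership), `voxel_size`,
#'   `cylinder` (center, diameter, z range) and `height` (mm). For a density
#'   stack: the stack with voxels outside the cylinder set to 0 plus a
#'   `region` field.
#' @export
extract_cylinder <- function(x, voxel_size_mm = NULL, center_xy = NULL,
                             diameter_mm = NULL, z_start = 0, z_end = NULL) {
  if (inherits(x, "density_stack") || inherits(x, "gray_stack")) {
    voxel_size_mm <- x$voxel_size
    vox <- x$voxels
  } else {
    if (is.null(voxel_size_mm)) stop("voxel_size_mm required for a bare array")
    vox <- x
  }
  d <- dim(vox)
  if (is.null(z_end)) z_end <- d[3]
  if (z_start < 0 || z_end > d[3] || z_start >= z_end)
    stop("slice range outside stack: need 0 <= z_start < z_end <= n_slices")
  if (is.null(center_xy)) center_xy <- c(d[1] / 2, d[2] / 2)
  h <- voxel_size_mm
  if (is.null(diameter_mm)) diameter_mm <- min(d[1], d[2]) * h
  r_vox <- diameter_mm / (2 * h)
  if (center_xy[1] - r_vox < -1e-9 || center_xy[1] + r_vox > d[1] + 1e-9 ||
      center_xy[2] - r_vox < -1e-9 || center_xy[2] + r_vox > d[2] + 1e-9)
    stop("cylinder does not fit the grid in-plane")
  rr <- (seq_len(d[1]) - 0.5) - center_xy[1]
  cc <- (seq_len(d[2]) - 0.5) - center_xy[2]
  disc <- outer(rr^2, cc^2, `+`) <= r_vox^2
  region <- array(FALSE, d)
  zin <- (z_start + 1):z_end
  region[, , zin] <- disc
  geom <- list(center_xy = center_xy, diameter_mm = diameter_mm,
               z_start = z_start, z_end = z_end)
  if (inherits(x, "density_stack")) {
    vox[!region] <- 0
    out <- density_stack(vox, voxel_size_mm)
    out$region <- region
    out$cylinder <- geom
    return(out)
  }
  mask <- vox & region
  structure(list(mask = mask, region = region, voxel_size = voxel_size_mm,
                 cylinder = geom, height = (z_end - z_start) * h),
            class = "trab_roi")
}

#' @export
print.trab_roi <- function(x, ...) {
  cat(sprintf(
    "<trab_roi> D = %.3f mm, height = %.3f mm (slices %d..%d), BV/TV = %.1f%%\n",
    x$cylinder$diameter_mm, x$height, x$cylinder$z_start + 1, x$cylinder$z_end,
    100 * sum(x$mask) / max(1, sum(x$region))))
  invisible(x)
}

# slice offsets of the ROI (1-based slice indices)
roi_slices <- function(roi) (roi$cylinder$z_start + 1):roi$cylinder$z_end

# crop mask/region to the ROI slice range
roi_crop <- function(roi) {
  zi <- roi_slices(roi)
  list(mask = roi$mask[, , zi, drop = FALSE],
       region = roi$region[, , zi, drop = FALSE])
}
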