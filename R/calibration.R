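#' Fit a density calibration from two phantom anchors
#'
#' Micro-CT gray values are converted to mineral-equivalent density by an
#' affine map fitted through two hydroxyapatite phantom readings of known
#' density (typically 0.250 and 0.750 g/cm^3). The map reproduces both
#' anchors exactly.
#'
#' Optionally the anchors can be expressed on the Hounsfield scale instead of
#' raw gray level by first mapping gray to HU with [gray_to_hu()] (anchored at
#' HU_air = -1000, HU_water = 0); the fitted calibration is then applied to
#' HU-transformed values.
#'
#' @param anchors 2x2 matrix (or list of two length-2 vectors) of
#'   (mean gray value, density g/cm^3) pairs.
#' @param hu_anchors optional length-2 vector `c(gray_air, gray_water)`; when
#'   given, anchor gray values and subsequently calibrated stacks are mapped
#'   gray -> HU before the affine density map is applied.
#' @return object of class `density_calibration` with fields `slope`
#'   ((g/cm^3) per gray level or per HU), `intercept` (g/cm^3), `anchors`
#'   and `hu_anchors`.
#' @export
fit_density_calibration <- function(anchors, hu_anchors = NULL) {
  if (is.list(anchors)) anchors <- do.call(rbind, anchors)
  anchors <- as.matrix(anchors)
  stopifnot(nrow(anchors) == 2, ncol(anchors) == 2)
  g <- anchors[, 1]
  d <- anchors[, 2]
  if (!is.null(hu_anchors)) {
    stopifnot(length(hu_anchors) == 2)
    g <- gray_to_hu(g, hu_anchors[1], hu_anchors[2])
  }
  if (g[1] == g[2])
    stop("degenerate calibration: anchor gray values are equal")
  slope <- (d[2] - d[1]) / (g[2] - g[1])
  intercept <- d[1] - slope * g[1]
  structure(list(slope = slope, intercept = intercept,
                 anchors = anchors, hu_anchors = hu_anchors),
            class = "density_calibration")
}

#' @export
print.density_calibration <- function(x, ...) {
  cat(sprintf("<density_calibration> density = %.6g * %s + %.6g g/cm^3\n",
              x$slope, if (is.null(x$hu_anchors)) "gray" else "HU", x$intercept))
  invisible(x)
}

#' Map gray levels to Hounsfield units
#'
#' Affine map fixed by the convention HU(air) = -1000 and HU(water) = 0.
#'
#' @param gray gray values.
#' @param gray_air,gray_water gray levels measured in air and water.
#' @return Hounsfield units.
#' @export
gray_to_hu <- function(gray, gray_air, gray_water) {
  if (gray_air == gray_water) stop("degenerate HU anchors")
  1000 * (gray - gray_water) / (gray_water - gray_air)
}

#' Predict density from gray values
#'
#' @param object a `density_calibration`.
#' @param gray gray values (HU conversion, if configured, is applied first).
#' @param clamp clamp negative densities to zero (default TRUE: density is
#'   physical; marrow and air can fall below the affine fit's zero crossing).
#' @param ... unused.
#' @return densities in g/cm^3.
#' @export
predict.density_calibration <- function(object, gray, clamp = TRUE, ...) {
  if (!is.null(object$hu_anchors))
    gray <- gray_to_hu(gray, object$hu_anchors[1], object$hu_anchors[2])
  d <- object$slope * gray + object$intercept
  if (clamp) d[d < 0] <- 0
  d
}

#' Calibrate a gray stack to density
#'
#' Applies the fitted affine gray-to-density map voxelwise; negative
#' densities are clamped to 0.
#'
#' @param stack a [gray_stack()].
#' @param calib a [fit_density_calibration()] result.
#' @return a [density_stack()].
#' @export
apply_calibration <- function(stack, calib) {
  stopifnot(inherits(stack, "gray_stack"), inherits(calib, "density_calibration"))
  d <- predict(calib, stack$voxels)
  dim(d) <- dim(stack$voxels)
  density_stack(d, stack$voxel_size)
}

#' Write / read a calibration as JSON
#'
#' @param calib a `density_calibration`.
#' @param path JSON file path.
#' @return `path` (write) or the calibration (read).
#' @export
write_calibration <- function(calib, path) {
  jsonlite::write_json(list(slope = calib$slope, intercept = calib$intercept,
                            anchors = calib$anchors, hu_anchors = calib$hu_anchors),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(slope = x$slope, intercept = x$intercept,
                 anchors = as.matrix(x$anchors),
                 hu_anchors = x$hu_anchors),
            class = "density_calibration")
}
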