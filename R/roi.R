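#' Region-of-interest mask aligned to a reference volume
#'
#' @param mask logical 3D array with the same shape as `reference`.
#' @param reference the [image_volume] defining the grid (normally the CT,
#'   since targets are CT-delineated).
#' @param name ROI label, e.g. `"GTV1"`.
#' @param density_g_cm3 tissue mass density used for voxel mass. Default 1.0
#'   (water); see [hu_to_density()] for a CT-derived alternative.
#' @return an object of class `roi_mask` with fields `mask`, `name`,
#'   `voxel_volume` (mm^3) and `voxel_mass` (kg).
#' @export
roi_mask <- function(mask, reference, name = "ROI", density_g_cm3 = 1.0) {
  if (!identical(dim(mask), dim(reference$data)))
    stop("mask shape must equal reference shape")
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("empty ROI: '", name, "' contains no voxels")
  if (density_g_cm3 <= 0) stop("density must be positive")
  vv <- voxel_volume_mm3(reference)
  structure(
    list(mask = mask, name = name, voxel_volume = vv,
         voxel_mass = density_g_cm3 * vv * 1e-6),  # g/cm^3 * mm^3 -> kg
    class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask '%s'> %d voxels, %.1f mm^3 each (%.3g kg)\n",
              x$name, sum(x$mask), x$voxel_volume, x$voxel_mass))
  invisible(x)
}

#' Number of voxels in an ROI
#' @param roi a [roi_mask].
#' @return integer count.
#' @export
roi_size <- function(roi) sum(roi$mask)

#' CT number to mass density
#'
#' Three-point piecewise-linear calibration through (HU, g/cm^3) anchors for
#' air, water and cortical bone; values outside the anchors are clamped.
#'
#' @param hu numeric HU values.
#' @param calibration 2-column matrix of (HU, density) anchor points.
#' @return densities in g/cm^3.
#' @export
hu_to_density <- function(hu,
                          calibration = cbind(hu = c(-1000, 0, 1000),
                                              density = c(0.0012, 1.0, 1.8))) {
  stats::approx(calibration[, 1], calibration[, 2], xout = hu,
                rule = 2)$y
}

#' Rasterize planar contours (or a mask volume) onto a reference grid
#'
#' A voxel belongs to the ROI iff its center lies inside the polygon drawn on
#' its slice (even-odd rule; no partial-voxel weighting). Contours are given
#' in patient coordinates: a list of closed polygons, each a list with
#' numeric vectors `x`, `y` (mm, at least 3 vertices) and scalar `z` (mm);
#' the polygon applies to the reference slice whose center is nearest to `z`.
#' Alternatively a MASK-modality [image_volume] on the reference grid is
#' thresholded at 0.5.
#'
#' @param contours contour list as described, or an [image_volume] mask.
#' @param reference [image_volume] defining the output grid.
#' @param name ROI label.
#' @param density_g_cm3 passed to [roi_mask()].
#' @return a [roi_mask].
#' @export
rasterize_roi <- function(contours, reference, name = "ROI",
                          density_g_cm3 = 1.0) {
  if (inherits(contours, "image_volume")) {
    return(roi_mask(contours$data > 0.5, reference, name, density_g_cm3))
  }
  dm <- dim(reference$data)
  mask <- array(FALSE, dm)
  xc <- axis_centers(reference, 1)
  yc <- axis_centers(reference, 2)
  zc <- axis_centers(reference, 3)
  grid_x <- rep(xc, times = dm[2])
  grid_y <- rep(yc, each = dm[1])
  for (ct in contours) {
    if (length(ct$x) < 3 || length(ct$y) < 3)
      stop("contour with fewer than 3 points")
    k <- which.min(abs(zc - ct$z))
    if (abs(zc[k] - ct$z) > reference$spacing[3])
      stop("contour at z=", ct$z, " mm lies outside the reference extent")
    if (any(ct$x < min(xc) - reference$spacing[1]) ||
        any(ct$x > max(xc) + reference$spacing[1]) ||
        any(ct$y < min(yc) - reference$spacing[2]))
      stop("contour extends outside the reference extent")
    inside <- pracma::inpolygon(grid_x, grid_y, ct$x, ct$y,
                                boundary = TRUE)
    mask[, , k] <- mask[, , k] | matrix(inside, dm[1], dm[2])
  }
  if (!any(mask)) stop("empty ROI: no voxel center falls inside '",
                       name, "'")
  roi_mask(mask, reference, name, density_g_cm3)
}
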