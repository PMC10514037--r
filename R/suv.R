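#' PET acquisition context for SUV computation
#'
#' Metadata needed to convert PET voxel intensity to body-weight SUV:
#' injected activity, body weight, the tracer half-life, and the decay
#' interval between the activity measurement and the scan. Times may be
#' given as `POSIXct` or as numeric minutes; the signed difference
#' `measurement_time - scan_time` enters the decay factor, so a measurement
#' taken before the scan (the usual case) yields a factor below 1 and a
#' correspondingly larger SUV.
#'
#' @param injected_dose_bq injected activity in Bq, > 0.
#' @param body_weight_kg patient body weight in kg, > 0.
#' @param measurement_time,scan_time `POSIXct` or numeric minutes.
#' @param half_life_min tracer half-life in minutes; default 109.771
#'   (fluorine-18).
#' @param acf attenuation correction factor: scalar 1 (default) for
#'   reconstruction-corrected data, or a scalar/per-voxel factor for raw
#'   data.
#' @return an object of class `suv_context`.
#' @export
suv_context <- function(injected_dose_bq, body_weight_kg,
                        measurement_time = 0, scan_time = 0,
                        half_life_min = 109.771, acf = 1) {
  if (injected_dose_bq <= 0) stop("injected dose must be positive")
  if (body_weight_kg <= 0) stop("body weight must be positive")
  if (half_life_min <= 0) stop("half-life must be positive")
  dt_min <- if (inherits(measurement_time, "POSIXct"))
    as.numeric(difftime(measurement_time, scan_time, units = "mins"))
  else as.numeric(measurement_time) - as.numeric(scan_time)
  structure(list(injected_dose_bq = injected_dose_bq,
                 body_weight_kg = body_weight_kg,
                 dt_min = dt_min, half_life_min = half_life_min,
                 acf = acf),
            class = "suv_context")
}

#' Per-voxel standardized uptake value map
#'
#' `SUV(V) = intensity(V) * ACF * body_weight / (injected_dose *
#' 2^(-dt / half_life))` with `dt = measurement_time - scan_time` in
#' minutes. Body-weight SUV, units kg/ml.
#'
#' @param pet PET [image_volume] (attenuation-corrected intensities, or raw
#'   with `ctx$acf` supplied).
#' @param ctx an [suv_context].
#' @return an [image_volume] with modality `"SUV"`.
#' @export
compute_suv_map <- function(pet, ctx) {
  stopifnot(inherits(pet, "image_volume"), inherits(ctx, "suv_context"))
  decay <- 2^(-ctx$dt_min / ctx$half_life_min)
  suv <- pet$data * ctx$acf * ctx$body_weight_kg /
    (ctx$injected_dose_bq * decay)
  image_volume(suv, pet$spacing, pet$origin, pet$direction, "SUV")
}

#' Mean SUV over an ROI
#'
#' Unweighted arithmetic mean over the ROI voxels (all voxels share one
#' volume).
#'
#' @param suv SUV [image_volume].
#' @param roi a [roi_mask] on the same grid.
#' @return scalar mean SUV.
#' @export
suv_mean <- function(suv, roi) {
  if (!identical(dim(suv$data), dim(roi$mask)))
    stop("SUV map and ROI are on different grids")
  mean(suv$data[roi$mask])
}

#' Per-voxel tumor-to-normal ratio map
#'
#' Divides the SUV of each tumor voxel by the mean SUV of a normal-tissue
#' ROI, generalizing the ROI-level TNR = SUV_mean,tumor / SUV_mean,normal to
#' voxels; the mean of the map equals the ROI-level TNR by construction.
#'
#' @param suv SUV [image_volume] (on the grid where the tumor is delineated,
#'   normally the CT grid).
#' @param tumor,normal [roi_mask]s on the same grid.
#' @return an object of class `tnr_map`: `values` (per tumor voxel, in array
#'   order), `roi` (the tumor mask), `baseline_suv_mean` and `summary`
#'   (min/max/mean).
#' @export
compute_tnr_map <- function(suv, tumor, normal) {
  base <- suv_mean(suv, normal)
  if (base <= 0) stop("normal-tissue baseline SUV must be positive")
  values <- suv$data[tumor$mask] / base
  structure(list(values = values, roi = tumor, baseline_suv_mean = base,
                 summary = c(min = min(values), max = max(values),
                             mean = mean(values))),
            class = "tnr_map")
}

#' @export
print.tnr_map <- function(x, ...) {
  cat(sprintf("<tnr_map '%s'> %d voxels, TNR %.2f-%.2f, mean %.2f\n",
              x$roi$name, length(x$values), x$summary["min"],
              x$summary["max"], x$summary["mean"]))
  invisible(x)
}

#' Construct a TNR map directly from per-voxel values
#'
#' Used by the homogeneous-boron mode (every voxel set to the ROI mean TNR)
#' and by tests with prescribed fields.
#'
#' @param values per-voxel TNR over the ROI (recycled if scalar).
#' @param roi a [roi_mask].
#' @param baseline_suv_mean baseline recorded for provenance.
#' @return a `tnr_map`.
#' @export
tnr_map_from_values <- function(values, roi, baseline_suv_mean = 1) {
  values <- rep_len(values, roi_size(roi))
  if (any(values < 0)) stop("TNR values must be non-negative")
  structure(list(values = values, roi = roi,
                 baseline_suv_mean = baseline_suv_mean,
                 summary = c(min = min(values), max = max(values),
                             mean = mean(values))),
            class = "tnr_map")
}

#' TNR-volume histogram
#'
#' Bin counts of the per-voxel TNR plus the cumulative volume fraction of
#' the ROI with TNR at or above each bin's lower edge (the TNR-volume
#' histogram); the cumulative curve starts at 1 at the lowest edge and is
#' non-increasing.
#'
#' @param tnr a `tnr_map`.
#' @param n_bins number of equal-width bins (>= 1).
#' @param range bin range; defaults to the value range (degenerate ranges
#'   are widened symmetrically by 0.5).
#' @return data.frame with `bin_low`, `bin_high`, `count`,
#'   `cum_volume_fraction`.
#' @export
tnr_histogram <- function(tnr, n_bins = 20, range = NULL) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  v <- tnr$values
  if (is.null(range)) range <- c(min(v), max(v))
  if (diff(range) == 0) range <- range + c(-0.5, 0.5)
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  idx <- findInterval(v, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  cum <- vapply(edges[-length(edges)],
                function(e) mean(v >= e), numeric(1))
  data.frame(bin_low = edges[-length(edges)], bin_high = edges[-1],
             count = counts, cum_volume_fraction = cum)
}
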