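#' Cumulative dose-volume histogram with dose statistics
#'
#' Builds the cumulative DVH of the weighted dose rate over an ROI (equal
#' voxel volumes) and the four standard statistics: the single-voxel
#' extrema `d_max` and `d_min`, the mean `d_mean`, and `d_80`, the dose
#' rate covering 80% of the volume. Coverage statistics are computed
#' bin-free by linear interpolation on the descending-sorted voxel doses at
#' rank `coverage * N`; the binned curve is reported alongside for
#' plotting/export.
#'
#' @param dose a `dose_field` (its `d_bnct` component is used) or a numeric
#'   3D array of dose rates.
#' @param roi a [roi_mask] on the same grid.
#' @param n_bins number of uniform bins for the exported curve.
#' @param coverage volume coverage for the prescription statistic
#'   (default 0.8).
#' @return an object of class `dvh_result`: `dose_axis`,
#'   `volume_fraction` (fraction of ROI receiving >= dose), and `stats`
#'   with `d_max`, `d_min`, `d_mean`, `d_80`.
#' @export
compute_dvh <- function(dose, roi, n_bins = 200, coverage = 0.8) {
  d <- if (inherits(dose, "dose_field")) dose$d_bnct else dose
  if (!identical(dim(d), dim(roi$mask)))
    stop("dose field and ROI are on different grids")
  v <- d[roi$mask]
  stats <- c(d_max = max(v), d_min = min(v), d_mean = mean(v),
             d_80 = dose_at_coverage(v, coverage))
  axis <- seq(0, max(v), length.out = n_bins + 1)
  frac <- vapply(axis, function(t) mean(v >= t), numeric(1))
  structure(list(dose_axis = axis, volume_fraction = frac, stats = stats,
                 coverage = coverage),
            class = "dvh_result")
}

#' @export
print.dvh_result <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "<dvh_result> d_max %.4g, d_min %.4g, d_mean %.4g, d_%d %.4g\n",
    s["d_max"], s["d_min"], s["d_mean"], round(100 * x$coverage),
    s["d_80"]))
  invisible(x)
}

#' Dose rate at a given volume coverage
#'
#' The dose received by at least `coverage` of the voxels, by linear
#' interpolation between ranks of the descending-sorted doses at rank
#' `coverage * N` (clamped to `[1, N]`).
#'
#' @param values per-voxel doses.
#' @param coverage volume fraction in (0, 1].
#' @return interpolated dose.
#' @export
dose_at_coverage <- function(values, coverage = 0.8) {
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  s <- sort(values, decreasing = TRUE)
  n <- length(s)
  r <- min(max(coverage * n, 1), n)
  lo <- floor(r); hi <- ceiling(r)
  if (lo == hi) s[lo] else s[lo] + (r - lo) * (s[hi] - s[lo])
}

#' Percent difference between two statistics
#'
#' The reporting convention used throughout the comparison tables:
#' `100 * (hetero - homo) / homo`, sign retained, rounded to one decimal at
#' display.
#'
#' @param homo,hetero the two values.
#' @param digits decimals to round to (NULL for unrounded).
#' @return percent difference.
#' @export
percent_difference <- function(homo, hetero, digits = 1) {
  p <- 100 * (hetero - homo) / homo
  if (is.null(digits)) p else round(p, digits)
}

#' Component percentages at a voxel
#'
#' Each weighted component expressed against the sum of the three
#' components at that voxel; sums to 100 up to rounding.
#'
#' @param components numeric vector (boron, neutron, photon weighted dose
#'   rates).
#' @param digits decimals to round to (NULL for unrounded).
#' @return percentages.
#' @export
component_percentages <- function(components, digits = 1) {
  p <- 100 * components / sum(components)
  if (is.null(digits)) p else round(p, digits)
}

# weighted components of a dose_field at one (masked) voxel position
weighted_components_at <- function(field, pos) {
  w <- field$weights
  c(d_b = w$cbe * field$d_phy_b10[pos],
    d_n = w$rbe_n * field$d_phy_n[pos],
    d_p = w$rbe_p * field$d_phy_p[pos])
}

#' Compare homogeneous- and heterogeneous-boron dose fields over an ROI
#'
#' The machinery behind the dose-rate comparison tables: for each method
#' the four DVH statistics; a difference row `100 * (hetero - homo) / homo`
#' per statistic; and for each method the component breakdown (TNR and
#' weighted boron/neutron/photon dose rates with percentages) at the voxels
#' where the weighted total attains its maximum and minimum.
#'
#' @param homo,hetero `dose_field`s computed on the same grid.
#' @param roi the [roi_mask] both were evaluated for.
#' @param tnr_homo,tnr_hetero `tnr_map`s giving the per-voxel TNR each
#'   method assumed (optional; NA reported if absent).
#' @param scale multiply reported dose rates by this factor (default 100:
#'   Gy-Eq/s -> cGy-Eq/s, the conventional reporting unit).
#' @return an object of class `method_comparison` with data.frames `stats`
#'   (per method + difference row) and `components` (per extremum/method +
#'   difference rows), plus both `dvh_result`s.
#' @export
compare_methods <- function(homo, hetero, roi, tnr_homo = NULL,
                            tnr_hetero = NULL, scale = 100) {
  if (!identical(dim(homo$d_bnct), dim(hetero$d_bnct)) ||
      !identical(dim(homo$d_bnct), dim(roi$mask)))
    stop("dose fields and ROI are on different grids")
  dvh_homo <- compute_dvh(homo, roi)
  dvh_hetero <- compute_dvh(hetero, roi)

  sh <- dvh_homo$stats * scale
  st <- dvh_hetero$stats * scale
  stats <- data.frame(
    roi = roi$name,
    method = c("homo", "hetero", "difference_pct"),
    d_max = c(sh["d_max"], st["d_max"],
              percent_difference(sh["d_max"], st["d_max"])),
    d_min = c(sh["d_min"], st["d_min"],
              percent_difference(sh["d_min"], st["d_min"])),
    d_mean = c(sh["d_mean"], st["d_mean"],
               percent_difference(sh["d_mean"], st["d_mean"])),
    d_80 = c(sh["d_80"], st["d_80"],
             percent_difference(sh["d_80"], st["d_80"])),
    row.names = NULL)

  mask_idx <- which(roi$mask)
  tnr_at <- function(tnr, which_voxel) {
    if (is.null(tnr)) return(NA_real_)
    tnr$values[match(which_voxel, mask_idx)]
  }
  one_extreme <- function(kind) {
    pick <- function(field) {
      v <- field$d_bnct[roi$mask]
      mask_idx[if (kind == "d_max") which.max(v) else which.min(v)]
    }
    vx_h <- pick(homo); vx_t <- pick(hetero)
    comp_h <- weighted_components_at(homo, vx_h) * scale
    comp_t <- weighted_components_at(hetero, vx_t) * scale
    data.frame(
      dose_category = kind,
      method = c("homo", "hetero", "difference_pct"),
      tnr = c(tnr_at(tnr_homo, vx_h), tnr_at(tnr_hetero, vx_t),
              percent_difference(tnr_at(tnr_homo, vx_h),
                                 tnr_at(tnr_hetero, vx_t))),
      d_b = c(comp_h["d_b"], comp_t["d_b"],
              percent_difference(comp_h["d_b"], comp_t["d_b"])),
      d_n = c(comp_h["d_n"], comp_t["d_n"],
              percent_difference(comp_h["d_n"], comp_t["d_n"])),
      d_p = c(comp_h["d_p"], comp_t["d_p"],
              percent_difference(comp_h["d_p"], comp_t["d_p"])),
      pct_b = c(component_percentages(comp_h, NULL)["d_b"],
                component_percentages(comp_t, NULL)["d_b"], NA),
      pct_n = c(component_percentages(comp_h, NULL)["d_n"],
                component_percentages(comp_t, NULL)["d_n"], NA),
      pct_p = c(component_percentages(comp_h, NULL)["d_p"],
                component_percentages(comp_t, NULL)["d_p"], NA),
      row.names = NULL)
  }
  components <- rbind(one_extreme("d_max"), one_extreme("d_min"))
  structure(list(stats = stats, components = components,
                 dvh_homo = dvh_homo, dvh_hetero = dvh_hetero,
                 scale = scale),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("Dose-rate statistics (cGy-Eq/s; difference row in %):\n")
  print(x$stats, digits = 4)
  invisible(x)
}

#' Extract a 2D dose-map slice
#'
#' A plane of the weighted (bioequivalent) or unweighted (physical) dose
#' rate, with the in-plane physical extent for plotting.
#'
#' @param field a `dose_field`.
#' @param axis slicing axis (1, 2 or 3).
#' @param index 1-based slice index along `axis`.
#' @param kind `"bioequivalent"` (weighted total) or `"physical"`
#'   (unweighted component sum).
#' @return list with `map` (2D matrix), `axes` (the two in-plane axes),
#'   `extent_mm` (ranges of the in-plane voxel centers) and `kind`.
#' @export
dose_slice <- function(field, axis = 3, index,
                       kind = c("bioequivalent", "physical")) {
  kind <- match.arg(kind)
  dm <- dim(field$d_bnct)
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3")
  if (index < 1 || index > dm[axis])
    stop("slice index ", index, " out of range [1, ", dm[axis], "]")
  vol <- if (kind == "bioequivalent") field$d_bnct
         else field$d_phy_b10 + field$d_phy_n + field$d_phy_p
  sl <- switch(axis,
               vol[index, , ], vol[, index, ], vol[, , index])
  in_plane <- setdiff(1:3, axis)
  geom <- field$geometry
  extent <- lapply(in_plane, function(a) range(axis_centers(geom, a)))
  list(map = sl, axes = in_plane, extent_mm = extent, kind = kind)
}

#' Write a DVH curve as CSV
#' @param dvh a `dvh_result`.
#' @param path output CSV path.
#' @param scale factor applied to the dose axis (default 100 for
#'   cGy-Eq/s).
#' @return `path`, invisibly.
#' @export
write_dvh_csv <- function(dvh, path, scale = 100) {
  utils::write.csv(data.frame(dose = dvh$dose_axis * scale,
                              volume_fraction = dvh$volume_fraction),
                   path, row.names = FALSE)
  invisible(path)
}
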