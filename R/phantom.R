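#' Synthetic phantom specification
#'
#' Describes a digital phantom with known ground truth: a water-equivalent
#' CT-resolution anatomy containing a spherical tumor with a prescribed TNR
#' field, and a PET image derived from that truth by Gaussian PSF blurring
#' and block-average downsampling to a coarser grid — the voxel-size
#' mismatch (about 1 mm CT vs about 5 mm in-plane PET in clinical brain
#' protocols) that produces the partial-volume effect. Optional Poisson
#' noise; off by default so unit tests are deterministic.
#'
#' @param ct_shape CT grid dimensions (voxels).
#' @param ct_spacing CT voxel size, mm.
#' @param pet_factor integer downsampling factor per axis (PET spacing =
#'   `pet_factor * ct_spacing`, so PET is never finer than CT).
#' @param tumor_center tumor center, mm (default: grid center).
#' @param tumor_radius tumor radius, mm.
#' @param tnr_field truth TNR field inside the tumor:
#'   `list(type = "uniform", t = 2.5)`,
#'   `list(type = "gradient", t_lo =, t_hi =)` (linear along x across the
#'   tumor extent),
#'   `list(type = "gaussian", t_peak =, sigma_mm =)` (peak at the center,
#'   decaying toward the baseline), or
#'   `list(type = "bimodal", t1 =, t2 =)` (two halves split at the center
#'   plane along x).
#' @param psf_fwhm_mm isotropic PET point-spread FWHM, mm.
#' @param noise `"none"` or `"poisson"`.
#' @param noise_scale expected PET counts per unit activity per voxel for
#'   Poisson noise.
#' @param baseline_suv SUV of normal tissue (TNR 1), default 1.
#' @param seed RNG seed used when noise is enabled.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(ct_shape = c(60, 60, 20),
                         ct_spacing = c(1, 1, 3),
                         pet_factor = c(5, 5, 1),
                         tumor_center = NULL, tumor_radius = 10,
                         tnr_field = list(type = "gradient",
                                          t_lo = 1.64, t_hi = 3.90),
                         psf_fwhm_mm = 5, noise = c("none", "poisson"),
                         noise_scale = 1e4, baseline_suv = 1, seed = 1L) {
  noise <- match.arg(noise)
  pet_factor <- as.integer(pet_factor)
  if (any(pet_factor < 1)) stop("pet_factor must be >= 1 per axis")
  if (any(ct_shape %% pet_factor != 0))
    stop("ct_shape must be divisible by pet_factor per axis")
  extent <- ct_shape * ct_spacing
  if (is.null(tumor_center)) tumor_center <- extent / 2
  if (any(tumor_center - tumor_radius < 0) ||
      any(tumor_center + tumor_radius > extent))
    stop("tumor extends outside the phantom grid")
  if (tumor_radius <= 0) stop("tumor radius must be positive")
  structure(list(ct_shape = as.integer(ct_shape), ct_spacing = ct_spacing,
                 pet_factor = pet_factor, tumor_center = tumor_center,
                 tumor_radius = tumor_radius, tnr_field = tnr_field,
                 psf_fwhm_mm = psf_fwhm_mm, noise = noise,
                 noise_scale = noise_scale, baseline_suv = baseline_suv,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# truth TNR value at physical coordinates (matrix n x 3), given the spec
truth_tnr_at <- function(spec, xyz) {
  d2 <- rowSums(sweep(xyz, 2, spec$tumor_center)^2)
  inside <- d2 <= spec$tumor_radius^2
  tnr <- rep(1, nrow(xyz))
  f <- spec$tnr_field
  tnr[inside] <- switch(
    f$type,
    uniform = f$t,
    gradient = {
      x0 <- spec$tumor_center[1] - spec$tumor_radius
      frac <- (xyz[inside, 1] - x0) / (2 * spec$tumor_radius)
      f$t_lo + (f$t_hi - f$t_lo) * pmin(pmax(frac, 0), 1)
    },
    gaussian = 1 + (f$t_peak - 1) * exp(-d2[inside] / (2 * f$sigma_mm^2)),
    bimodal = ifelse(xyz[inside, 1] < spec$tumor_center[1], f$t1, f$t2),
    stop("unknown TNR field type: ", f$type))
  tnr
}

# separable Gaussian blur with edge-renormalized kernels (convolving a
# constant returns the constant exactly, so the baseline is preserved)
gaussian_blur3 <- function(data, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    kern <- exp(-((-half:half)^2) / (2 * s^2))
    data <- blur_axis(data, kern, ax)
  }
  data
}

blur_axis <- function(data, kern, ax) {
  dm <- dim(data)
  perm <- c(ax, setdiff(1:3, ax))
  m <- matrix(aperm(data, perm), dm[ax])
  n <- dm[ax]; half <- (length(kern) - 1L) / 2L
  out <- matrix(0, n, ncol(m))
  wsum <- numeric(n)
  for (o in -half:half) {
    w <- kern[o + half + 1L]
    valid <- seq_len(n) + o >= 1L & seq_len(n) + o <= n
    out[valid, ] <- out[valid, ] + w * m[seq_len(n)[valid] + o, ]
    wsum[valid] <- wsum[valid] + w
  }
  out <- out / wsum
  aperm(array(out, dm[perm]), order(perm))
}

# block-average downsample by integer factors (mean-preserving)
block_downsample <- function(data, factor) {
  dm <- dim(data)
  out_dm <- dm %/% factor
  idx <- function(a) (seq_len(dm[a]) - 1L) %/% factor[a]
  # accumulate into the coarse grid
  coarse <- array(0, out_dm)
  grp <- 1L + idx(1)[slice.index(data, 1)] +
    out_dm[1] * (idx(2)[slice.index(data, 2)] +
                 out_dm[2] * idx(3)[slice.index(data, 3)])
  sums <- tapply(as.vector(data), as.vector(grp), sum)
  coarse[as.integer(names(sums))] <- sums / prod(factor)
  coarse
}

#' Build a synthetic CT/PET phantom with known ground truth
#'
#' The truth activity is `baseline_suv * TNR` on the CT grid; the PET image
#' is that truth blurred with the PSF, block-averaged to the PET grid and
#' (optionally) Poisson-resampled. PET intensities and the returned
#' acquisition context are chosen consistently, so running
#' [compute_suv_map()] on the PET volume recovers the activity scale and
#' the normal-tissue SUV equals `baseline_suv`.
#'
#' @param spec a [phantom_spec].
#' @return list with `ct`, `pet`, `truth_tnr` ([image_volume]s), `tumor`
#'   and `normal` ([roi_mask]s on the CT grid), `ctx` (the [suv_context]),
#'   and `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$ct_shape
  ct <- image_volume(array(0, dm), spec$ct_spacing, modality = "CT")

  idx <- as.matrix(expand.grid(i = seq_len(dm[1]) - 1,
                               j = seq_len(dm[2]) - 1,
                               k = seq_len(dm[3]) - 1))
  xyz <- voxel_to_physical(ct, idx)
  tnr_vals <- truth_tnr_at(spec, xyz)
  truth <- image_volume(array(tnr_vals, dm), spec$ct_spacing,
                        modality = "TNR")
  tumor_mask <- array(rowSums(sweep(xyz, 2, spec$tumor_center)^2) <=
                        spec$tumor_radius^2, dm)
  tumor <- roi_mask(tumor_mask, ct, "GTV")

  # normal-tissue ROI: a fixed cuboid near the low corner, away from the
  # tumor and its blur leakage but fully inside the PET extent (the first
  # PET voxel center sits (factor-1)/2 fine voxels in from the edge)
  nx <- pmax(2L, round(6 / spec$ct_spacing[1]))
  ny <- pmax(2L, round(6 / spec$ct_spacing[2]))
  off <- spec$pet_factor
  normal_mask <- array(FALSE, dm)
  normal_mask[off[1] + seq_len(nx), off[2] + seq_len(ny),
              pmin(off[3] + seq_len(dm[3] - 2 * off[3]), dm[3])] <- TRUE
  normal <- roi_mask(normal_mask, ct, "NORMAL")

  activity <- spec$baseline_suv * truth$data
  sigma_vox <- (spec$psf_fwhm_mm / 2.35482) / spec$ct_spacing
  blurred <- if (spec$psf_fwhm_mm > 0) gaussian_blur3(activity, sigma_vox)
             else activity
  pet_data <- block_downsample(blurred, spec$pet_factor)
  if (spec$noise == "poisson") {
    set.seed(spec$seed)
    counts <- stats::rpois(length(pet_data), pet_data * spec$noise_scale)
    pet_data <- array(counts / spec$noise_scale, dim(pet_data))
  }

  # PET geometry: coarse grid centered on the fine-grid blocks
  pet_spacing <- spec$ct_spacing * spec$pet_factor
  pet_origin <- ct$origin + (spec$pet_factor - 1) / 2 * spec$ct_spacing
  # intensity scale: SUV = intensity * bw / dose, so intensity carrying
  # dose/bw per unit activity makes compute_suv_map() return activity
  ctx <- suv_context(injected_dose_bq = 3.7e8, body_weight_kg = 70)
  intensity <- pet_data * ctx$injected_dose_bq / ctx$body_weight_kg
  pet <- image_volume(array(intensity, dim(pet_data)), pet_spacing,
                      pet_origin, modality = "PET")

  list(ct = ct, pet = pet, truth_tnr = truth, tumor = tumor,
       normal = normal, ctx = ctx, spec = spec)
}

#' Write phantom fixtures to disk
#'
#' NIfTI volumes (CT, PET, truth TNR, masks), a small synthetic DICOM
#' series of the CT for I/O tests, and a JSON sidecar with the acquisition
#' context and truth summary.
#'
#' @param phantom a [build_phantom()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(phantom$ct, file.path(dir, "ct.nii.gz"))
  write_volume(phantom$pet, file.path(dir, "pet.nii.gz"))
  write_volume(phantom$truth_tnr, file.path(dir, "truth_tnr.nii.gz"))
  msk <- function(m) image_volume(array(as.numeric(m), dim(m)),
                                  phantom$ct$spacing, phantom$ct$origin,
                                  phantom$ct$direction, "MASK")
  write_volume(msk(phantom$tumor$mask), file.path(dir, "tumor.nii.gz"))
  write_volume(msk(phantom$normal$mask), file.path(dir, "normal.nii.gz"))
  write_dicom_series(phantom$ct, file.path(dir, "ct_dicom"))
  truth_roi <- phantom$truth_tnr$data[phantom$tumor$mask]
  jsonlite::write_json(
    list(ctx = unclass(phantom$ctx),
         truth = list(mean_tnr = mean(truth_roi),
                      min_tnr = min(truth_roi),
                      max_tnr = max(truth_roi))),
    file.path(dir, "phantom.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
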