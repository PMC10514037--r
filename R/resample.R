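#' Resample a volume onto the grid of a reference volume
#'
#' Trilinear interpolation of `src` at the physical voxel centers of
#' `reference` (both in the LPS patient frame; an optional rigid transform
#' maps reference coordinates into the src frame). Reference voxels whose
#' mapped position falls outside the src extent are filled with 0; their
#' count is recorded in the `n_outside` attribute so silent truncation is
#' auditable. Trilinear interpolation reproduces any affine field exactly,
#' so resampling a constant or linear ramp is exact.
#'
#' @param src [image_volume] to be interpolated.
#' @param reference [image_volume] whose grid defines the output.
#' @param transform optional 4x4 rigid transform (reference frame -> src
#'   frame); default identity.
#' @return an [image_volume] on the reference grid, modality inherited from
#'   `src`, with attribute `n_outside`.
#' @export
resample_to <- function(src, reference, transform = diag(4)) {
  dm_ref <- dim(reference$data)
  dm_src <- dim(src$data)

  # physical centers of all reference voxels
  idx <- as.matrix(expand.grid(i = seq_len(dm_ref[1]) - 1,
                               j = seq_len(dm_ref[2]) - 1,
                               k = seq_len(dm_ref[3]) - 1))
  phys <- voxel_to_physical(reference, idx)
  phys <- t(transform[1:3, 1:3] %*% t(phys) + transform[1:3, 4])
  cont <- physical_to_voxel(src, phys)  # continuous 0-based src indices

  eps <- 1e-9
  inside <- cont[, 1] >= -eps & cont[, 1] <= dm_src[1] - 1 + eps &
            cont[, 2] >= -eps & cont[, 2] <= dm_src[2] - 1 + eps &
            cont[, 3] >= -eps & cont[, 3] <= dm_src[3] - 1 + eps
  if (!any(inside))
    stop("resample_to: src and reference extents do not overlap")

  out <- numeric(nrow(cont))
  cc <- cont[inside, , drop = FALSE]
  cc[, 1] <- pmin(pmax(cc[, 1], 0), dm_src[1] - 1)
  cc[, 2] <- pmin(pmax(cc[, 2], 0), dm_src[2] - 1)
  cc[, 3] <- pmin(pmax(cc[, 3], 0), dm_src[3] - 1)
  i0 <- pmin(floor(cc[, 1]), dm_src[1] - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(cc[, 2]), dm_src[2] - 2); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(cc[, 3]), dm_src[3] - 2); k0 <- pmax(k0, 0)
  if (dm_src[1] == 1) i0 <- rep(0, nrow(cc))
  if (dm_src[2] == 1) j0 <- rep(0, nrow(cc))
  if (dm_src[3] == 1) k0 <- rep(0, nrow(cc))
  fx <- cc[, 1] - i0; fy <- cc[, 2] - j0; fz <- cc[, 3] - k0

  d <- src$data
  at <- function(di, dj, dk) {
    ii <- pmin(i0 + di, dm_src[1] - 1)
    jj <- pmin(j0 + dj, dm_src[2] - 1)
    kk <- pmin(k0 + dk, dm_src[3] - 1)
    d[1 + ii + dm_src[1] * (jj + dm_src[2] * kk)]
  }
  out[inside] <-
    at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(1, 0, 0) * fx       * (1 - fy) * (1 - fz) +
    at(0, 1, 0) * (1 - fx) * fy       * (1 - fz) +
    at(1, 1, 0) * fx       * fy       * (1 - fz) +
    at(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    at(1, 0, 1) * fx       * (1 - fy) * fz +
    at(0, 1, 1) * (1 - fx) * fy       * fz +
    at(1, 1, 1) * fx       * fy       * fz

  res <- image_volume(array(out, dm_ref), spacing = reference$spacing,
                      origin = reference$origin,
                      direction = reference$direction,
                      modality = src$modality)
  attr(res, "n_outside") <- sum(!inside)
  res
}
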