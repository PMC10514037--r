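#' Oriented 3D image volume
#'
#' The common currency of every pipeline stage: a 3D scalar grid with
#' physical geometry. Values live at voxel centers; the physical position of
#' 0-based voxel index `(i,j,k)` is
#' `origin + direction %*% (spacing * c(i,j,k))`, in the DICOM LPS patient
#' frame (millimetres).
#'
#' @param data numeric 3D array. Units depend on `modality`: HU for CT, raw
#'   scanner intensity for PET, Gy-Eq/s for DOSE, dimensionless for TNR.
#' @param spacing length-3 positive numeric, voxel size in mm per axis.
#' @param origin length-3 numeric, physical coordinate (mm) of the center of
#'   voxel (0,0,0).
#' @param direction 3x3 orthonormal orientation matrix (columns are the
#'   patient-space directions of the array axes).
#' @param modality one of `"CT"`, `"PET"`, `"DOSE"`, `"MASK"`, `"TNR"`,
#'   `"SUV"`, `"FLUX"`.
#' @return an object of class `image_volume`.
#' @examples
#' vol <- image_volume(array(0, c(4, 4, 2)), spacing = c(1, 1, 3))
#' voxel_volume_mm3(vol)
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0),
                         direction = diag(3),
                         modality = c("CT", "PET", "DOSE", "MASK", "TNR",
                                      "SUV", "FLUX")) {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be three finite values (mm)")
  direction <- matrix(as.numeric(direction), 3L, 3L)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("'direction' must be orthonormal (within 1e-6)")
  structure(
    list(data = data, spacing = spacing, origin = origin,
         direction = direction, modality = modality),
    class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s> %s voxels, spacing %s mm, origin (%s) mm\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Voxel volume in cubic millimetres
#' @param vol an [image_volume].
#' @return scalar, mm^3.
#' @export
voxel_volume_mm3 <- function(vol) prod(vol$spacing)

#' Physical coordinates of voxel centers
#'
#' @param vol an [image_volume].
#' @param index 0-based integer voxel index, an n x 3 matrix (or length-3
#'   vector).
#' @return n x 3 matrix of LPS coordinates in mm.
#' @export
voxel_to_physical <- function(vol, index) {
  index <- rbind(index)
  t(vol$direction %*% (t(index) * vol$spacing) + vol$origin)
}

#' Map physical coordinates to continuous 0-based voxel indices
#' @param vol an [image_volume].
#' @param xyz n x 3 matrix of LPS mm coordinates.
#' @return n x 3 matrix of continuous voxel indices.
#' @export
physical_to_voxel <- function(vol, xyz) {
  xyz <- rbind(xyz)
  t((t(vol$direction) %*% (t(xyz) - vol$origin)) / vol$spacing)
}

# physical center coordinates of all voxels along one axis (0-based grid,
# identity-direction fast path not assumed by callers)
axis_centers <- function(vol, axis) {
  n <- dim(vol$data)[axis]
  vol$origin[axis] + vol$spacing[axis] * (seq_len(n) - 1)
}

#' Read an image volume from disk
#'
#' NIfTI files are read through RNifti; the stored RAS affine is converted to
#' the package's LPS convention. DICOM series (a directory of single-frame
#' explicit-VR little-endian slices) are read with the minimal codec in this
#' package: slices are sorted along the slice normal and must be uniformly
#' spaced, and the PET rescale slope/intercept are applied.
#'
#' @param path file (NIfTI) or directory (DICOM series).
#' @param kind `"nifti"` or `"dicom-series"`.
#' @param modality modality tag to assign; for DICOM, defaults to the
#'   Modality tag in the files.
#' @return an [image_volume].
#' @export
read_volume <- function(path, kind = c("nifti", "dicom-series"),
                        modality = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (kind == "nifti") {
    img <- RNifti::readNifti(path)
    aff <- structure(RNifti::xform(img), imagedim = NULL)
    if (is.null(modality)) modality <- "CT"
    nifti_affine_to_volume(as.array(img), unclass(aff)[1:3, , drop = FALSE],
                           modality)
  } else {
    read_dicom_series(path, modality = modality)
  }
}

# RAS->LPS: negate first two rows of the affine
nifti_affine_to_volume <- function(data, aff_ras, modality) {
  aff <- aff_ras
  aff[1:2, ] <- -aff[1:2, ]
  lin <- aff[, 1:3, drop = FALSE]
  spacing <- sqrt(colSums(lin^2))
  image_volume(data, spacing = spacing, origin = aff[, 4],
               direction = sweep(lin, 2, spacing, "/"), modality = modality)
}

#' Write an image volume to a NIfTI file
#'
#' The LPS geometry is stored as an RAS sform/qform so other NIfTI readers
#' agree on physical positions. Mask volumes are written as uint8.
#'
#' @param vol an [image_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  datatype <- if (vol$modality == "MASK") "uint8" else "double"
  img <- RNifti::asNifti(vol$data, datatype = datatype)
  lin <- vol$direction %*% diag(vol$spacing)
  aff <- rbind(cbind(lin, vol$origin), c(0, 0, 0, 1))
  aff[1:2, ] <- -aff[1:2, ]  # LPS -> RAS
  RNifti::`sform<-`(img, structure(aff, code = 1L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}
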