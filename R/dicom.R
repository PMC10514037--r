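# Minimal DICOM slice codec: uncompressed single-frame grayscale images in
# explicit-VR little-endian transfer syntax, one file per axial slice.
# Covers exactly the geometry/rescale tags the pipeline needs (CT and PET
# exports of this kind); it is not a general DICOM implementation and makes
# no attempt at sequences, compressed syntaxes or multi-frame objects.

DICOM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

# ---- writing ----------------------------------------------------------------

dcm_pad <- function(raw, pad = as.raw(0L)) {
  if (length(raw) %% 2L == 1L) c(raw, pad) else raw
}

dcm_element <- function(group, element, vr, value_raw) {
  value_raw <- dcm_pad(value_raw, if (vr %in% c("UI", "OB")) as.raw(0L)
                                  else charToRaw(" "))
  head <- c(writeBin(c(group, element), raw(), size = 2, endian = "little"))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4, endian = "little"),
      value_raw)
  } else {
    c(head, charToRaw(vr),
      writeBin(length(value_raw), raw(), size = 2, endian = "little"),
      value_raw)
  }
}

dcm_str <- function(x) charToRaw(paste(x, collapse = "\\"))
dcm_ds <- function(x) dcm_str(sprintf("%.10g", x))
dcm_us <- function(x) writeBin(as.integer(x), raw(), size = 2,
                               endian = "little")

# Encode one slice. `slice` is an nx x ny numeric matrix (x fastest, matching
# DICOM row-major pixel order with rows along y). Values are stored as
# unsigned 16-bit with a rescale slope/intercept chosen to cover the range.
write_dicom_slice <- function(path, slice, spacing, position, direction,
                              modality) {
  rng <- range(slice)
  integerish <- max(abs(slice - round(slice))) < 1e-9
  if (integerish && diff(rng) <= 65535) {
    slope <- 1; intercept <- floor(rng[1])
  } else if (diff(rng) == 0) {
    slope <- 1; intercept <- rng[1]
  } else {
    slope <- diff(rng) / 60000; intercept <- rng[1]
  }
  stored <- as.integer(round((slice - intercept) / slope))
  pix <- writeBin(stored, raw(), size = 2, endian = "little")

  meta <- dcm_element(0x0002L, 0x0010L, "UI", charToRaw(DICOM_TS_EXPLICIT_LE))
  meta <- c(dcm_element(0x0002L, 0x0000L, "UL",
                        writeBin(length(meta), raw(), size = 4,
                                 endian = "little")),
            meta)

  iop <- c(direction[, 1], direction[, 2])  # row dir (x), column dir (y)
  body <- c(
    dcm_element(0x0008L, 0x0060L, "CS", charToRaw(modality)),
    dcm_element(0x0018L, 0x0050L, "DS", dcm_ds(spacing[3])),
    dcm_element(0x0020L, 0x0032L, "DS", dcm_ds(position)),
    dcm_element(0x0020L, 0x0037L, "DS", dcm_ds(iop)),
    dcm_element(0x0028L, 0x0002L, "US", dcm_us(1L)),
    dcm_element(0x0028L, 0x0010L, "US", dcm_us(ncol(slice))),  # Rows (y)
    dcm_element(0x0028L, 0x0011L, "US", dcm_us(nrow(slice))),  # Columns (x)
    dcm_element(0x0028L, 0x0030L, "DS", dcm_ds(c(spacing[2], spacing[1]))),
    dcm_element(0x0028L, 0x0100L, "US", dcm_us(16L)),
    dcm_element(0x0028L, 0x0101L, "US", dcm_us(16L)),
    dcm_element(0x0028L, 0x0102L, "US", dcm_us(15L)),
    dcm_element(0x0028L, 0x0103L, "US", dcm_us(0L)),
    dcm_element(0x0028L, 0x1052L, "DS", dcm_ds(intercept)),
    dcm_element(0x0028L, 0x1053L, "DS", dcm_ds(slope)),
    dcm_element(0x7FE0L, 0x0010L, "OW", pix))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

#' Write an image volume as a synthetic DICOM series
#'
#' One explicit-VR little-endian single-frame file per axial slice, carrying
#' the geometry and rescale tags that [read_volume()] consumes. Intended for
#' fixtures and interchange of phantom data, not for clinical archiving.
#'
#' @param vol an [image_volume].
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_dicom_series <- function(vol, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nz <- dim(vol$data)[3]
  for (k in seq_len(nz)) {
    pos <- drop(voxel_to_physical(vol, c(0, 0, k - 1)))
    write_dicom_slice(file.path(dir, sprintf("slice_%04d.dcm", k)),
                      vol$data[, , k], vol$spacing, pos, vol$direction,
                      vol$modality)
  }
  invisible(dir)
}

# ---- reading ----------------------------------------------------------------

read_dicom_file <- function(path) {
  raw <- readBin(path, raw(), n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  pos <- 133L
  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 8L <= length(raw)) {
    grp <- readBin(raw[pos:(pos + 1)], "integer", size = 2, signed = FALSE,
                   endian = "little")
    ele <- readBin(raw[(pos + 2):(pos + 3)], "integer", size = 2,
                   signed = FALSE, endian = "little")
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% long_vrs) {
      len <- readBin(raw[(pos + 8):(pos + 11)], "integer", size = 4,
                     endian = "little")
      val_start <- pos + 12L
    } else {
      len <- readBin(raw[(pos + 6):(pos + 7)], "integer", size = 2,
                     signed = FALSE, endian = "little")
      val_start <- pos + 8L
    }
    val <- if (len > 0) raw[val_start:(val_start + len - 1L)] else raw(0)
    tags[[sprintf("%04X,%04X", grp, ele)]] <- list(vr = vr, value = val)
    pos <- val_start + len
  }
  tags
}

tag_str <- function(tags, key) {
  v <- tags[[key]]
  if (is.null(v)) return(NULL)
  trimws(rawToChar(v$value))
}
tag_ds <- function(tags, key) {
  s <- tag_str(tags, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
tag_us <- function(tags, key) {
  v <- tags[[key]]
  if (is.null(v)) return(NULL)
  readBin(v$value, "integer", size = 2, signed = FALSE, endian = "little")
}

read_dicom_series <- function(dir, modality = NULL) {
  files <- sort(list.files(dir, pattern = "\\.dcm$", full.names = TRUE))
  if (length(files) == 0) stop("no .dcm files in ", dir)
  parsed <- lapply(files, read_dicom_file)

  first <- parsed[[1]]
  iop <- tag_ds(first, "0020,0037")
  xdir <- iop[1:3]; ydir <- iop[4:6]
  normal <- c(xdir[2] * ydir[3] - xdir[3] * ydir[2],
              xdir[3] * ydir[1] - xdir[1] * ydir[3],
              xdir[1] * ydir[2] - xdir[2] * ydir[1])
  zpos <- vapply(parsed, function(t) sum(tag_ds(t, "0020,0032") * normal),
                 numeric(1))
  ord <- order(zpos)
  parsed <- parsed[ord]; files <- files[ord]; zpos <- zpos[ord]

  if (length(files) > 1) {
    dz <- diff(zpos)
    ref <- stats::median(dz)
    bad <- which(abs(dz - ref) > 1e-3 * abs(ref))
    if (length(bad) > 0)
      stop("non-uniform slice spacing at ", basename(files[bad[1] + 1]),
           sprintf(" (gap %.4g mm, expected %.4g mm)", dz[bad[1]], ref))
    slice_spacing <- ref
  } else {
    slice_spacing <- tag_ds(first, "0018,0050")
    if (is.null(slice_spacing)) slice_spacing <- 1
  }

  nx <- tag_us(first, "0028,0011")  # Columns
  ny <- tag_us(first, "0028,0010")  # Rows
  ps <- tag_ds(first, "0028,0030")  # row spacing (y), column spacing (x)
  slices <- lapply(parsed, function(t) {
    stored <- readBin(t[["7FE0,0010"]]$value, "integer", size = 2,
                      signed = FALSE, endian = "little", n = nx * ny)
    slope <- tag_ds(t, "0028,1053"); if (is.null(slope)) slope <- 1
    icpt <- tag_ds(t, "0028,1052"); if (is.null(icpt)) icpt <- 0
    matrix(stored * slope + icpt, nx, ny)
  })
  data <- array(unlist(slices), dim = c(nx, ny, length(slices)))

  mod <- modality
  if (is.null(mod)) mod <- tag_str(first, "0008,0060")
  if (is.null(mod) || !mod %in% c("CT", "PET", "DOSE", "MASK", "TNR", "SUV"))
    stop("unsupported or missing DICOM modality: ",
         if (is.null(mod)) "<none>" else mod)
  image_volume(data, spacing = c(ps[2], ps[1], slice_spacing),
               origin = tag_ds(parsed[[1]], "0020,0032"),
               direction = cbind(xdir, ydir, normal), modality = mod)
}
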