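# NIfTI I/O via RNifti; DICOM series reading in R/dicom.R.

tet_to_nifti <- function(vol) {
  s <- spacing_of(vol)
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- s
  # LPS voxel axes expressed in the NIfTI RAS+ world
  m <- rbind(c(-s[1], 0, 0, -vol$origin[1]),
             c(0, -s[2], 0, -vol$origin[2]),
             c(0, 0, s[3], vol$origin[3]),
             c(0, 0, 0, 1))
  RNifti::`qform<-`(img, structure(m, code = 2L))
}

nifti_to_tet <- function(img, as_mask = FALSE) {
  codes <- try(c(img$qform_code, img$sform_code), silent = TRUE)
  has_xform <- !inherits(codes, "try-error") && any(codes > 0, na.rm = TRUE)
  if (has_xform) {
    RNifti::orientation(img) <- TETVOL_ORIENTATION
  } else {
    warning("volume carries no qform/sform; assuming it is already in the ",
            TETVOL_ORIENTATION, " orientation")
  }
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
  if (length(d) != 3L) stop("expected a 3D volume")
  attributes(arr) <- NULL   # drop niftiImage metadata attributes
  dim(arr) <- d
  # pixdim and offsets are stored as float32; snap to their 7 significant
  # digits so that values like 0.8 mm round-trip exactly
  s <- signif(RNifti::pixdim(img)[1:3], 7)
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (!inherits(xf, "try-error") && has_xform)
    signif(c(-xf[1, 4], -xf[2, 4], xf[3, 4]), 7) else c(0, 0, 0)
  if (as_mask) {
    storage.mode(arr) <- "integer"
    label_mask(arr, spacing = s, origin = origin)
  } else {
    image_volume(arr, spacing = s, origin = origin)
  }
}

#' Read a CT volume from disk
#'
#' Reads a NIfTI file or a single-series directory of DICOM slices and
#' returns the volume reoriented to the canonical LPS convention (axis 1
#' towards patient left, axis 2 posterior, axis 3 superior), with spacing
#' taken from the file metadata.
#'
#' @param path File (NIfTI) or directory (DICOM series).
#' @param format `"nifti"` or `"dicom_series"`; default guessed from `path`.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom_series")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_series" else "nifti"
  if (format == "nifti") {
    if (!file.exists(path)) stop("NIfTI file not found: ", path)
    nifti_to_tet(RNifti::readNifti(path))
  } else {
    read_dicom_series(path)
  }
}

#' Read a label mask from a NIfTI file
#'
#' As [read_volume()] but coerces voxels to integer labels.
#'
#' @param path NIfTI file.
#' @return A [label_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  nifti_to_tet(RNifti::readNifti(path), as_mask = TRUE)
}

#' Write a label mask (or image) to NIfTI
#'
#' Re-reading the file reproduces labels, spacing and orientation exactly.
#'
#' @param mask A [label_mask()] or [image_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly `path`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "tet_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write to non-existent directory: ", dir)
  RNifti::writeNifti(tet_to_nifti(mask), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
write_volume <- write_mask
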