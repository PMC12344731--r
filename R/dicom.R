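# Minimal reader for uncompressed single-frame CT DICOM series.
# Supports implicit and explicit VR little endian, 16-bit pixel data,
# axis-aligned (non-oblique) slice orientations. Read-only; no DICOM writing.

dicom_uid_implicit <- "1.2.840.10008.1.2"
dicom_uid_explicit <- "1.2.840.10008.1.2.1"

read_u16 <- function(raw, off) {
  readBin(raw[(off + 1):(off + 2)], "integer", size = 2, endian = "little",
          signed = FALSE)
}
read_u32 <- function(raw, off) {
  lo <- read_u16(raw, off); hi <- read_u16(raw, off + 2)
  lo + hi * 65536
}

# One pass over a DICOM file, collecting the handful of tags we use.
parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 132L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  wanted <- c("0002,0010", "0020,000e", "0020,0032", "0020,0037",
              "0028,0010", "0028,0011", "0028,0030", "0028,0100",
              "0028,0103", "0028,1052", "0028,1053", "7fe0,0010")
  out <- list()
  off <- 132L
  explicit <- TRUE   # file meta group is always explicit little endian
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (off + 8 <= length(raw)) {
    group <- read_u16(raw, off); elem <- read_u16(raw, off + 2)
    if (group != 2L && identical(out$transfer_syntax, dicom_uid_implicit))
      explicit <- FALSE
    tag <- sprintf("%04x,%04x", group, elem)
    if (explicit || group == 2L) {
      vr <- rawToChar(raw[(off + 5):(off + 6)])
      if (vr %in% long_vrs) {
        len <- read_u32(raw, off + 8); body <- off + 12L
      } else {
        len <- read_u16(raw, off + 6); body <- off + 8L
      }
    } else {
      vr <- NA_character_
      len <- read_u32(raw, off + 4); body <- off + 8L
    }
    if (len == 4294967295) stop("undefined-length elements are not supported: ", path)
    if (tag %in% wanted) {
      bytes <- raw[(body + 1):(body + len)]
      out[[tag]] <- bytes
      if (tag == "0002,0010")
        out$transfer_syntax <- sub("\\s+$", "", gsub("\\x00", "", rawToChar(bytes)))
    }
    if (tag == "7fe0,0010") { out$pixel_len <- len; break }
    off <- body + len
  }
  ts <- out$transfer_syntax
  if (is.null(ts) || !ts %in% c(dicom_uid_implicit, dicom_uid_explicit))
    stop("unsupported transfer syntax (only uncompressed little endian): ", path)
  dcm_str <- function(tag) {
    b <- out[[tag]]
    if (is.null(b)) return(NULL)
    sub("\\s+$", "", gsub("\\x00", "", rawToChar(b)))
  }
  dcm_ds <- function(tag) {
    s <- dcm_str(tag)
    if (is.null(s)) return(NULL)
    as.numeric(strsplit(s, "\\\\")[[1]])
  }
  dcm_us <- function(tag) {
    b <- out[[tag]]
    if (is.null(b)) return(NULL)
    readBin(b, "integer", size = 2, endian = "little", signed = FALSE)
  }
  rows <- dcm_us("0028,0010"); cols <- dcm_us("0028,0011")
  bits <- dcm_us("0028,0100")
  if (is.null(rows) || is.null(cols) || is.null(out[["7fe0,0010"]]))
    stop("missing image data in DICOM file: ", path)
  if (!identical(bits, 16L)) stop("only 16-bit DICOM pixel data is supported: ", path)
  signed <- identical(dcm_us("0028,0103"), 1L)
  px <- readBin(out[["7fe0,0010"]], "integer", n = rows * cols, size = 2,
                endian = "little", signed = signed)
  slope <- dcm_ds("0028,1053"); intercept <- dcm_ds("0028,1052")
  if (is.null(slope)) slope <- 1; if (is.null(intercept)) intercept <- 0
  list(series_uid = dcm_str("0020,000e"),
       ipp = dcm_ds("0020,0032"),
       iop = dcm_ds("0020,0037"),
       pixel_spacing = dcm_ds("0028,0030"),
       # array indexed [column, row]: fastest-varying pixel index is the column
       pixels = array(px * slope + intercept, dim = c(cols, rows)))
}

#' Read a single-series DICOM directory as a canonical volume
#'
#' Slices are sorted along the slice normal; the slice gap must be uniform to
#' within 1e-3 mm (silent resampling would corrupt volume measurements, so
#' irregular series are rejected). Oblique acquisitions (direction cosines not
#' aligned with the patient axes) and multi-series directories are rejected.
#'
#' @param path Directory containing the slices of one series.
#' @return An [image_volume()] in the canonical LPS orientation.
#' @export
read_dicom_series <- function(path) {
  if (!dir.exists(path)) stop("DICOM series directory not found: ", path)
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  is_dicom <- vapply(files, function(f) {
    if (file.size(f) < 132) return(FALSE)
    identical(rawToChar(readBin(f, "raw", n = 132)[129:132]), "DICM")
  }, logical(1))
  files <- files[is_dicom]
  if (length(files) == 0L) stop("no DICOM files found in: ", path)
  slices <- lapply(files, parse_dicom_file)

  uids <- unique(vapply(slices, function(s) s$series_uid %||% "", character(1)))
  if (length(uids) > 1L)
    stop("directory contains more than one DICOM series: ", path)

  iop <- slices[[1]]$iop
  if (is.null(iop) || length(iop) != 6L)
    stop("missing ImageOrientationPatient in series: ", path)
  row_dir <- iop[1:3]; col_dir <- iop[4:6]
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])

  pos <- vapply(slices, function(s) sum(s$ipp * normal), numeric(1))
  ord <- order(pos)
  slices <- slices[ord]; pos <- pos[ord]
  if (length(slices) < 2L) stop("a DICOM series needs at least two slices: ", path)
  gaps <- diff(pos)
  if (max(gaps) - min(gaps) > 1e-3)
    stop(sprintf("non-uniform slice spacing in %s (gaps %.4f-%.4f mm); refusing to resample",
                 path, min(gaps), max(gaps)))
  dz <- mean(gaps)
  if (dz <= 0) stop("degenerate slice positions in series: ", path)

  ps <- slices[[1]]$pixel_spacing   # (row spacing, column spacing)
  arr <- array(0, dim = c(dim(slices[[1]]$pixels), length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]$pixels

  # voxel axes in patient (LPS) coordinates: axis1 = along rows (columns
  # increase), axis2 = along columns, axis3 = slice normal
  dirs <- cbind(row_dir, col_dir, normal)
  spac <- c(ps[2], ps[1], dz)
  if (any(apply(abs(dirs), 2, max) < 0.999))
    stop("oblique DICOM series are not supported: ", path)

  perm <- integer(3); sgn <- integer(3)
  for (w in 1:3) {
    a <- which.max(abs(dirs[w, ]))
    perm[w] <- a; sgn[w] <- sign(dirs[w, a])
  }
  if (length(unique(perm)) != 3L) stop("degenerate orientation in series: ", path)
  arr <- aperm(arr, perm)
  shape <- dim(arr)
  for (w in 1:3) if (sgn[w] < 0) {
    idx <- rep(list(quote(expr = )), 3); idx[[w]] <- shape[w]:1
    arr <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  }
  # patient-space position of the voxel that became index (1,1,1)
  first0 <- ifelse(sgn > 0, 0, shape - 1)  # 0-based index on the permuted axes
  origin <- slices[[1]]$ipp
  for (w in 1:3) origin <- origin + first0[w] * spac[perm[w]] * dirs[, perm[w]]
  image_volume(arr, spacing = spac[perm],
               origin = c(origin[1], origin[2], origin[3]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
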