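#' @useDynLib tetvol, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rnorm sd pnorm wilcox.test
#' @importFrom utils combn read.csv write.csv head
"_PACKAGE"

# Canonical orientation used throughout: voxel axis 1 increases towards the
# patient's left (X), axis 2 towards posterior (Y), axis 3 towards superior
# (Z) -- the DICOM LPS patient convention. Every volume is reoriented to this
# on load, so the anatomical classification rules are deterministic.
TETVOL_ORIENTATION <- "LPS"

#' Voxel spacing in millimetres
#'
#' @param dx,dy,dz Edge length of one voxel along each canonical axis, in mm.
#' @return Numeric vector of length 3 with class `voxel_spacing`.
#' @examples
#' s <- voxel_spacing(1, 1, 1)
#' voxel_volume_cm3(s)  # 0.001
#' @export
voxel_spacing <- function(dx, dy = dx, dz = dx) {
  s <- as.numeric(c(dx, dy, dz))
  if (length(s) != 3L || anyNA(s) || any(s <= 0))
    stop("voxel spacing must be three strictly positive lengths (mm)")
  structure(s, names = c("dx", "dy", "dz"), class = "voxel_spacing")
}

#' Volume of a single voxel in cubic centimetres
#'
#' The quantity `v` used by the absolute volume difference: with spacing in
#' mm, `v = dx * dy * dz / 1000` cm^3.
#'
#' @param spacing A [voxel_spacing()] or an object carrying one.
#' @return Strictly positive scalar, cm^3.
#' @export
voxel_volume_cm3 <- function(spacing) {
  s <- spacing_of(spacing)
  prod(s) / 1000
}

spacing_of <- function(x) {
  if (inherits(x, "voxel_spacing")) return(unclass(x))
  if (is.list(x) && !is.null(x$spacing)) return(unclass(x$spacing))
  if (is.numeric(x) && length(x) == 3L) return(unclass(voxel_spacing(x[1], x[2], x[3])))
  stop("cannot extract a voxel spacing from this object")
}

new_geometry_volume <- function(data, spacing, origin, class) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("voxel data must be a 3D array")
  if (any(dim(data) < 1L)) stop("each axis needs at least one voxel")
  spacing <- voxel_spacing(spacing[1], spacing[2], spacing[3])
  origin <- as.numeric(origin)
  if (length(origin) != 3L || anyNA(origin))
    stop("origin must be a numeric 3-vector (mm)")
  structure(
    list(data = data, spacing = spacing, origin = origin,
         orientation = TETVOL_ORIENTATION),
    class = class)
}

#' 3D CT image volume
#'
#' A scalar (Hounsfield-unit-like) 3D volume on the canonical LPS orientation
#' with voxel spacing and physical origin.
#'
#' @param voxels 3D numeric array of intensities.
#' @param spacing [voxel_spacing()] or numeric 3-vector, mm.
#' @param origin Physical position (mm) of voxel (1,1,1); default zero.
#' @return An `image_volume` object.
#' @export
image_volume <- function(voxels, spacing = voxel_spacing(1), origin = c(0, 0, 0)) {
  storage.mode(voxels) <- "double"
  new_geometry_volume(voxels, spacing, origin, c("image_volume", "tet_volume"))
}

#' Integer label mask paired to an image volume
#'
#' Background is 0. A "binary" mask has labels in \{0, 1\}; multi-label masks
#' use one positive integer per lesion. Geometry (shape, spacing) must match
#' any paired [image_volume()].
#'
#' @param labels 3D array of non-negative integers.
#' @inheritParams image_volume
#' @return A `label_mask` object.
#' @export
label_mask <- function(labels, spacing = voxel_spacing(1), origin = c(0, 0, 0)) {
  if (is.logical(labels)) storage.mode(labels) <- "integer"
  if (any(labels < 0) || any(labels != round(labels)))
    stop("mask labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  new_geometry_volume(labels, spacing, origin, c("label_mask", "tet_volume"))
}

#' @export
print.tet_volume <- function(x, ...) {
  kind <- if (inherits(x, "label_mask")) "label_mask" else "image_volume"
  cat(sprintf("<%s> %s voxels, spacing %s mm, orientation %s\n",
              kind, paste(dim(x$data), collapse = "x"),
              paste(signif(spacing_of(x), 4), collapse = "x"),
              x$orientation))
  if (inherits(x, "label_mask")) {
    lab <- sort(unique(as.integer(x$data)))
    cat(sprintf("  labels: {%s}; foreground voxels: %d\n",
                paste(head(lab, 8L), collapse = ","), sum(x$data != 0L)))
  }
  invisible(x)
}

#' @export
dim.tet_volume <- function(x) dim(x$data)

is_binary_mask <- function(mask) {
  inherits(mask, "label_mask") && all(mask$data %in% c(0L, 1L))
}

#' Collapse a multi-label mask to binary foreground
#'
#' @param mask A [label_mask()].
#' @return A [label_mask()] with labels in \{0, 1\}.
#' @export
as_binary_mask <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  mask$data <- (mask$data != 0L) * 1L
  storage.mode(mask$data) <- "integer"
  mask
}

as_binary <- as_binary_mask

#' Check that two volumes share geometry
#'
#' Errors unless shape and spacing agree (spacing to 1e-6 mm).
#'
#' @param a,b `image_volume` or `label_mask` objects.
#' @param what Label used in the error message.
#' @return Invisibly `TRUE`.
#' @export
check_same_geometry <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data), dim(b$data)))
    stop(sprintf("geometry mismatch (%s): shapes %s vs %s", what,
                 paste(dim(a$data), collapse = "x"),
                 paste(dim(b$data), collapse = "x")))
  if (any(abs(spacing_of(a) - spacing_of(b)) > 1e-6))
    stop(sprintf("geometry mismatch (%s): spacings %s vs %s mm", what,
                 paste(spacing_of(a), collapse = "x"),
                 paste(spacing_of(b), collapse = "x")))
  invisible(TRUE)
}

#' Axis-aligned 3D bounding box, half-open
#'
#' Bounds are 0-based continuous voxel coordinates: voxel with R index
#' `(i,j,k)` occupies `[i-1, i) x [j-1, j) x [k-1, k)`. A box therefore
#' covers R indices `(lower+1):upper` on each axis, and `lower < upper`.
#'
#' @param lower,upper Integer 3-vectors, `lower < upper` per axis.
#' @return A `bbox3d` object.
#' @export
bbox3d <- function(lower, upper) {
  lower <- as.integer(lower); upper <- as.integer(upper)
  if (length(lower) != 3L || length(upper) != 3L || any(lower >= upper))
    stop("bbox3d requires lower < upper on every axis")
  structure(list(lower = lower, upper = upper), class = "bbox3d")
}

#' @export
print.bbox3d <- function(x, ...) {
  cat(sprintf("<bbox3d> [%s) x [%s) x [%s)\n",
              paste(c(x$lower[1], x$upper[1]), collapse = ","),
              paste(c(x$lower[2], x$upper[2]), collapse = ","),
              paste(c(x$lower[3], x$upper[3]), collapse = ",")))
  invisible(x)
}

#' Centre of a bounding box (0-based voxel coordinates, may be fractional)
#' @param bbox A [bbox3d()].
#' @return Numeric 3-vector `(lower + upper - 1) / 2`.
#' @export
bbox_center <- function(bbox) (bbox$lower + bbox$upper - 1) / 2

bbox_shape <- function(bbox) bbox$upper - bbox$lower

# R index ranges covered by a bbox
bbox_index_ranges <- function(bbox) {
  lapply(1:3, function(a) (bbox$lower[a] + 1L):bbox$upper[a])
}

bbox_extract <- function(arr, bbox) {
  r <- bbox_index_ranges(bbox)
  arr[r[[1]], r[[2]], r[[3]], drop = FALSE]
}

bbox_clip <- function(bbox, shape) {
  lo <- pmax(bbox$lower, 0L)
  up <- pmin(bbox$upper, as.integer(shape))
  if (any(lo >= up)) stop("bounding box lies outside the volume")
  bbox3d(lo, up)
}

bbox_expand <- function(bbox, margin) {
  margin <- as.integer(rep_len(margin, 3L))
  bbox3d(bbox$lower - margin, bbox$upper + margin)
}

# Tight bbox of TRUE entries of a logical array (0-based half-open)
bbox_of_foreground <- function(fg) {
  idx <- which(fg, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  bbox3d(apply(idx, 2, min) - 1L, apply(idx, 2, max))
}
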