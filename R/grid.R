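# Lung-relative 5x5x5 grid and the two cropping strategies: box crops around
# individual lesions and cell crops reused across a patient's scans.

#' Addressable cell of a lung grid
#'
#' @param i,j,k 0-based cell indices along X, Y, Z, each in `[0, divisions)`.
#' @param divisions Grid divisions per axis (for range checking).
#' @return A `grid_cell` with a human-readable label `"X{i}-Y{j}-Z{k}"`.
#' @export
grid_cell <- function(i, j, k, divisions = 5L) {
  idx <- as.integer(c(i, j, k))
  if (any(idx < 0L) || any(idx >= divisions))
    stop(sprintf("cell indices (%d,%d,%d) outside [0,%d)", idx[1], idx[2],
                 idx[3], divisions))
  structure(list(i = idx[1], j = idx[2], k = idx[3],
                 label = sprintf("X%d-Y%d-Z%d", idx[1], idx[2], idx[3])),
            class = "grid_cell")
}

#' @export
print.grid_cell <- function(x, ...) {
  cat(sprintf("<grid_cell %s>\n", x$label)); invisible(x)
}

#' @export
format.grid_cell <- function(x, ...) x$label

#' Build the lung-relative grid
#'
#' Partitions the (optionally padded) tight bounding box of the lung mask
#' into `divisions^3` cells with equal real-valued extents per axis. The grid
#' is always relative to the lungs, so it approximately retains
#' correspondence across a patient's scans.
#'
#' @param lung_mask Binary [label_mask()] of the lungs (nonzero = lung).
#' @param divisions Cells per axis; default 5 (a 5x5x5 grid, 125 cells).
#' @param pad_fraction Fraction of the lung span added to each side per axis
#'   (length 1 or 3), clipped to the volume; default 0 (tight box).
#' @return A `lung_grid` with fields `lung_bbox`, `divisions`, `boundaries`
#'   (per-axis increasing cut positions in 0-based voxel coordinates) and
#'   `volume_shape`.
#' @export
build_lung_grid <- function(lung_mask, divisions = 5L, pad_fraction = 0) {
  stopifnot(inherits(lung_mask, "label_mask"))
  divisions <- as.integer(divisions)
  if (divisions < 1L) stop("divisions must be >= 1")
  fg <- lung_mask$data != 0L
  bb <- bbox_of_foreground(fg)
  if (is.null(bb)) stop("lung mask is empty; cannot build a lung grid")
  pad <- rep_len(pad_fraction, 3L)
  span <- bb$upper - bb$lower
  lo <- pmax(floor(bb$lower - pad * span), 0)
  up <- pmin(ceiling(bb$upper + pad * span), dim(lung_mask$data))
  bb <- bbox3d(lo, up)
  boundaries <- lapply(1:3, function(a)
    seq(bb$lower[a], bb$upper[a], length.out = divisions + 1L))
  structure(list(lung_bbox = bb, divisions = divisions,
                 boundaries = boundaries,
                 volume_shape = dim(lung_mask$data)),
            class = "lung_grid")
}

#' @export
print.lung_grid <- function(x, ...) {
  cat(sprintf("<lung_grid> %d^3 cells over lung bbox [%s)-[%s)\n",
              x$divisions, paste(x$lung_bbox$lower, collapse = ","),
              paste(x$lung_bbox$upper, collapse = ",")))
  invisible(x)
}

# Per-axis cell indices (0-based) for 0-based voxel coordinates; NA outside
# the grid. `coords` is an n x 3 matrix.
cell_indices_of_coords <- function(grid, coords) {
  d <- grid$divisions
  out <- matrix(NA_integer_, nrow = nrow(coords), ncol = 3L)
  for (a in 1:3) {
    b <- grid$boundaries[[a]]
    x <- coords[, a]
    i <- findInterval(x, b) - 1L           # half-open intervals
    i[x >= b[d + 1L] | x < b[1L]] <- NA_integer_  # outside the lung bbox
    out[, a] <- i
  }
  out
}

#' Grid cell containing a voxel
#'
#' Interval assignment is half-open per axis with the last interval closed,
#' so every in-bbox voxel maps to exactly one cell.
#'
#' @param grid A [build_lung_grid()] result.
#' @param voxel_index 1-based R voxel index `(i, j, k)`.
#' @return A [grid_cell()], or `NULL` for voxels outside the lung bbox.
#' @export
cell_of_voxel <- function(grid, voxel_index) {
  stopifnot(inherits(grid, "lung_grid"))
  coord <- matrix(as.numeric(voxel_index) - 1, nrow = 1)  # 0-based
  idx <- cell_indices_of_coords(grid, coord)
  if (anyNA(idx)) return(NULL)
  grid_cell(idx[1], idx[2], idx[3], grid$divisions)
}

#' Cells containing any foreground of a lesion mask
#'
#' The training-time selection rule: the cells containing ground-truth
#' lesion voxels. A lesion spanning cell boundaries yields several cells.
#'
#' @param grid A `lung_grid`.
#' @param lesion_mask Binary [label_mask()] on the same volume.
#' @return List of [grid_cell()]s (empty, with a warning, if the lesion lies
#'   entirely outside the lung bbox).
#' @export
cells_containing_mask <- function(grid, lesion_mask) {
  stopifnot(inherits(grid, "lung_grid"), inherits(lesion_mask, "label_mask"))
  if (!identical(as.integer(dim(lesion_mask$data)), as.integer(grid$volume_shape)))
    stop("lesion mask shape does not match the grid's volume")
  idx <- which(lesion_mask$data != 0L)
  if (length(idx) == 0L) return(list())
  coords <- arrayInd(idx, .dim = dim(lesion_mask$data)) - 1L
  cells <- cell_indices_of_coords(grid, coords)
  keep <- stats::complete.cases(cells)
  if (!any(keep)) {
    warning("lesion lies entirely outside the lung grid")
    return(list())
  }
  uniq <- unique(cells[keep, , drop = FALSE])
  uniq <- uniq[order(uniq[, 1], uniq[, 2], uniq[, 3]), , drop = FALSE]
  lapply(seq_len(nrow(uniq)), function(r)
    grid_cell(uniq[r, 1], uniq[r, 2], uniq[r, 3], grid$divisions))
}

#' Voxel bounding box of one grid cell
#'
#' Real-valued cell boundaries are rounded outward to whole voxels so that
#' adjacent cells share no voxel and the cells tile the lung bbox exactly.
#'
#' @param grid A `lung_grid`.
#' @param cell A [grid_cell()].
#' @return A [bbox3d()].
#' @export
cell_bbox <- function(grid, cell) {
  stopifnot(inherits(grid, "lung_grid"), inherits(cell, "grid_cell"))
  idx <- c(cell$i, cell$j, cell$k)
  lo <- up <- integer(3)
  for (a in 1:3) {
    b <- grid$boundaries[[a]]
    lo[a] <- ceiling(b[idx[a] + 1L])
    up[a] <- ceiling(b[idx[a] + 2L])
  }
  if (any(lo >= up))
    stop(sprintf("grid cell %s contains no whole voxel (lung span too small for %d divisions)",
                 cell$label, grid$divisions))
  bbox3d(lo, up)
}

new_crop_region <- function(bbox, image_patch, mask_patch, provenance) {
  structure(list(bbox = bbox, image_patch = image_patch,
                 mask_patch = mask_patch, provenance = provenance),
            class = "crop_region")
}

#' @export
print.crop_region <- function(x, ...) {
  cat(sprintf("<crop_region %s> [%s)-[%s)%s\n", x$provenance$type,
              paste(x$bbox$lower, collapse = ","),
              paste(x$bbox$upper, collapse = ","),
              if (is.null(x$mask_patch)) "" else " +mask"))
  invisible(x)
}

#' Box crop around one lesion
#'
#' Extracts the 3D region of interest surrounding the maximum boundaries of
#' an individual lesion, expanded by a small margin per side (context for
#' the segmenter) and clipped to the volume. One box per lesion.
#'
#' @param image An [image_volume()].
#' @param lesion_bbox [bbox3d()] of the lesion (e.g. a component's `bbox`).
#' @param margin_voxels Margin per side, length 1 or 3; default 2.
#' @param mask Optional [label_mask()] cropped alongside the image.
#' @return A `crop_region` with `provenance$type == "box"`.
#' @export
box_crop <- function(image, lesion_bbox, margin_voxels = 2L, mask = NULL) {
  stopifnot(inherits(image, "image_volume"), inherits(lesion_bbox, "bbox3d"))
  bb <- bbox_clip(bbox_expand(lesion_bbox, margin_voxels), dim(image$data))
  mask_patch <- NULL
  if (!is.null(mask)) {
    check_same_geometry(image, mask, "box_crop image/mask")
    mask_patch <- bbox_extract(mask$data, bb)
  }
  new_crop_region(bb, bbox_extract(image$data, bb), mask_patch,
                  list(type = "box",
                       lesion_bbox = lesion_bbox,
                       margin_voxels = rep_len(as.integer(margin_voxels), 3L)))
}

#' Cell crop of one grid cell
#'
#' @param image An [image_volume()].
#' @param grid A `lung_grid` built on the same volume.
#' @param cell A [grid_cell()].
#' @param mask Optional [label_mask()] cropped alongside the image.
#' @return A `crop_region` with `provenance$type == "cell"`.
#' @export
cell_crop <- function(image, grid, cell, mask = NULL) {
  stopifnot(inherits(image, "image_volume"))
  if (!identical(as.integer(dim(image$data)), as.integer(grid$volume_shape)))
    stop("image shape does not match the grid's volume")
  bb <- cell_bbox(grid, cell)
  mask_patch <- NULL
  if (!is.null(mask)) {
    check_same_geometry(image, mask, "cell_crop image/mask")
    mask_patch <- bbox_extract(mask$data, bb)
  }
  new_crop_region(bb, bbox_extract(image$data, bb), mask_patch,
                  list(type = "cell", cell = cell, divisions = grid$divisions))
}

#' Paste a binary patch back onto a scan-sized canvas
#'
#' Reassembles per-crop inference into a scan-level mask. Overlapping pastes
#' combine by voxelwise OR (the segmentation task is binary).
#'
#' @param patch Binary 3D array (or patch-sized [label_mask()]) matching the
#'   bbox extents.
#' @param bbox [bbox3d()] placing the patch in the canvas.
#' @param canvas Either a 3D shape (integer 3-vector) for a fresh zero
#'   canvas, or an existing [label_mask()] to OR into.
#' @param spacing Spacing for a fresh canvas; default 1 mm isotropic.
#' @return A binary [label_mask()] of the canvas shape.
#' @export
paste_crop <- function(patch, bbox, canvas, spacing = voxel_spacing(1)) {
  if (inherits(patch, "label_mask")) patch <- patch$data
  if (inherits(canvas, "label_mask")) {
    out <- canvas
  } else {
    out <- label_mask(array(0L, dim = as.integer(canvas)), spacing = spacing)
  }
  shape <- dim(out$data)
  if (any(bbox$lower < 0L) || any(bbox$upper > shape))
    stop("paste bbox lies outside the canvas")
  if (!identical(as.integer(dim(patch)), as.integer(bbox_shape(bbox))))
    stop("patch shape does not match the bbox extents")
  r <- bbox_index_ranges(bbox)
  sub <- out$data[r[[1]], r[[2]], r[[3]], drop = FALSE]
  out$data[r[[1]], r[[2]], r[[3]]] <- (sub != 0L | patch != 0L) * 1L
  storage.mode(out$data) <- "integer"
  out
}
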