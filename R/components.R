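# Connected-component extraction and voxel-volume accounting.

#' One connected tumour region
#'
#' Built by [connected_components()] (or per label of a multi-label mask).
#' Carries the linear voxel indices (1-based, column-major), the voxel count
#' and the tight half-open bounding box whose centre is the `(Xt, Yt, Zt)`
#' used by the anatomical classification rules.
#'
#' @param component_id Integer id within its mask.
#' @param voxel_indices 1-based linear indices into the mask array.
#' @param shape Shape of the parent mask.
#' @return A `lesion_component` with fields `component_id`, `voxel_indices`,
#'   `size`, `bbox`.
#' @export
lesion_component <- function(component_id, voxel_indices, shape) {
  voxel_indices <- sort(as.integer(voxel_indices))
  if (length(voxel_indices) < 1L) stop("a lesion component needs >= 1 voxel")
  coords <- arrayInd(voxel_indices, .dim = shape)
  structure(
    list(component_id = as.integer(component_id),
         voxel_indices = voxel_indices,
         size = length(voxel_indices),
         bbox = bbox3d(apply(coords, 2, min) - 1L, apply(coords, 2, max)),
         shape = as.integer(shape)),
    class = "lesion_component")
}

#' @export
print.lesion_component <- function(x, ...) {
  ctr <- bbox_center(x$bbox)
  cat(sprintf("<lesion_component #%d> %d voxels, centre (%.1f, %.1f, %.1f)\n",
              x$component_id, x$size, ctr[1], ctr[2], ctr[3]))
  invisible(x)
}

#' Connected components of a binary mask
#'
#' Nonzero voxels are treated as foreground. Components are returned in a
#' deterministic order: descending voxel count, ties broken by the smallest
#' linear voxel index. The default 26-connectivity merges diagonally touching
#' voxels into one lesion (conservative for tumour identity).
#'
#' @param mask A [label_mask()] (nonzero = foreground).
#' @param connectivity 6, 18 or 26.
#' @return List of [lesion_component()]s (empty mask gives an empty list).
#' @export
connected_components <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "label_mask"))
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  fg <- mask$data != 0L
  if (!any(fg)) return(list())
  lab <- label_components_cpp(fg, dim(mask$data), as.integer(connectivity))
  split_labelled(lab, dim(mask$data))
}

# Order labelled regions (descending size, ties by lowest linear index) and
# wrap them as lesion_component objects.
split_labelled <- function(lab, shape) {
  idx <- which(lab != 0L)
  if (length(idx) == 0L) return(list())
  by_label <- split(idx, lab[idx])
  sizes <- lengths(by_label)
  firsts <- vapply(by_label, min, numeric(1))  # indices are pre-sorted by which()
  ord <- order(-sizes, firsts)
  by_label <- by_label[ord]
  lapply(seq_along(by_label), function(i)
    lesion_component(i, by_label[[i]], shape))
}

#' Per-label components of a multi-label mask
#'
#' Each positive label is treated as one lesion regardless of connectivity
#' (labels may touch). Ordering follows [connected_components()].
#'
#' @param mask A multi-label [label_mask()].
#' @return Named list of [lesion_component()]s; names are the original labels.
#' @export
label_components <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  idx <- which(mask$data != 0L)
  if (length(idx) == 0L) return(list())
  by_label <- split(idx, mask$data[idx])
  sizes <- lengths(by_label)
  firsts <- vapply(by_label, min, numeric(1))
  ord <- order(-sizes, firsts)
  by_label <- by_label[ord]
  out <- lapply(seq_along(by_label), function(i)
    lesion_component(i, by_label[[i]], dim(mask$data)))
  names(out) <- names(by_label)
  out
}

#' Foreground volume of a mask in cubic centimetres
#'
#' The number of foreground (nonzero) voxels times the single-voxel volume
#' `v` in cm^3.
#'
#' @param mask A [label_mask()].
#' @return Volume in cm^3.
#' @examples
#' m <- label_mask(array(c(rep(1L, 100), rep(0L, 900)), dim = c(10, 10, 10)))
#' mask_volume_cm3(m)  # 0.1
#' @export
mask_volume_cm3 <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  sum(mask$data != 0L) * voxel_volume_cm3(mask)
}

# Binary mask with only this component's voxels set
component_mask <- function(component, template) {
  arr <- array(0L, dim = dim(template$data))
  arr[component$voxel_indices] <- 1L
  label_mask(arr, spacing = spacing_of(template), origin = template$origin)
}
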