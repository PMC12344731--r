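# Rule-based anatomical classification of lesions as parenchymal,
# mediastinal or pleural from lung-mask coordinate quartiles. The cascade:
#   1. a lesion not bordering the lung boundary is parenchymal;
#   2. a bordering lesion whose bounding-box centre (Xt,Yt,Zt) satisfies
#      x25 <= Xt <= x75 and Yt <= y75 is mediastinal;
#   3. everything else is pleural.
# On the canonical orientation Y increases anterior -> posterior, so
# "Yt <= y75" excludes the posterior-most lung band, consistent with thymic
# tumours arising in the anterior mediastinum.

#' Coordinate quartiles of the lung segmentation
#'
#' 25th/75th percentiles of the X coordinates and 75th percentile of the Y
#' coordinates of lung foreground voxels (0-based voxel coordinates,
#' canonical orientation, combined left+right lungs). Percentiles use linear
#' interpolation between order statistics (type 7).
#'
#' @param lung_mask Binary [label_mask()] of the lungs.
#' @return A `lung_quartiles` list with `x25`, `x75`, `y75`.
#' @export
lung_quartiles <- function(lung_mask) {
  stopifnot(inherits(lung_mask, "label_mask"))
  idx <- which(lung_mask$data != 0L)
  if (length(idx) == 0L) stop("lung mask is empty; cannot compute quartiles")
  coords <- arrayInd(idx, .dim = dim(lung_mask$data)) - 1L
  structure(list(
    x25 = unname(quantile(coords[, 1], 0.25, type = 7)),
    x75 = unname(quantile(coords[, 1], 0.75, type = 7)),
    y75 = unname(quantile(coords[, 2], 0.75, type = 7)),
    percentile_method = "linear interpolation (type 7)"),
    class = "lung_quartiles")
}

#' @export
print.lung_quartiles <- function(x, ...) {
  cat(sprintf("<lung_quartiles> x25=%.2f x75=%.2f y75=%.2f\n",
              x$x25, x$x75, x$y75))
  invisible(x)
}

# Shift a logical array by one voxel along axis `a` (direction +/-1),
# padding with `fill`.
shift_logical <- function(arr, a, dir, fill = FALSE) {
  d <- dim(arr)
  out <- array(fill, dim = d)
  src <- dst <- lapply(d, seq_len)
  if (dir > 0) { dst[[a]] <- 2:d[a]; src[[a]] <- 1:(d[a] - 1L) }
  else         { dst[[a]] <- 1:(d[a] - 1L); src[[a]] <- 2:d[a] }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

#' One-voxel boundary shell of the lung mask
#'
#' Lung voxels with at least one 6-neighbour outside the lung foreground
#' (voxels on the volume edge count as boundary). This operationalizes "the
#' lung segmentation boundary" for the border test.
#'
#' @param lung_mask Binary [label_mask()].
#' @return Binary [label_mask()] of the shell.
#' @export
lung_boundary_shell <- function(lung_mask) {
  stopifnot(inherits(lung_mask, "label_mask"))
  fg <- lung_mask$data != 0L
  interior <- fg
  for (a in 1:3) for (dir in c(-1L, 1L))
    interior <- interior & shift_logical(fg, a, dir, fill = FALSE)
  out <- lung_mask
  out$data <- (fg & !interior) * 1L
  storage.mode(out$data) <- "integer"
  out
}

# 26-dilate a logical array by one voxel.
dilate26 <- function(arr) {
  out <- arr
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    t <- arr
    if (dx != 0) t <- shift_logical(t, 1L, dx)
    if (dy != 0) t <- shift_logical(t, 2L, dy)
    if (dz != 0) t <- shift_logical(t, 3L, dz)
    out <- out | t
  }
  out
}

#' Does a lesion border the lung boundary?
#'
#' Default mode: `TRUE` iff any lesion voxel lies on the shell or is
#' 26-adjacent to a shell voxel. This admits lesions lying just outside the
#' lung mask (pleural and mediastinal lesions are mostly extra-pulmonary).
#' Strict mode requires the lesion to intersect the shell itself.
#'
#' @param lesion A [lesion_component()] on the same geometry as the shell.
#' @param shell Binary [label_mask()] from [lung_boundary_shell()].
#' @param strict If `TRUE`, adjacency does not count; only intersection.
#' @return Logical scalar.
#' @export
borders_lung_boundary <- function(lesion, shell, strict = FALSE) {
  stopifnot(inherits(lesion, "lesion_component"), inherits(shell, "label_mask"))
  if (!identical(as.integer(lesion$shape), as.integer(dim(shell$data))))
    stop("lesion and shell are on different geometries")
  shell_fg <- shell$data != 0L
  if (strict) return(any(shell_fg[lesion$voxel_indices]))
  # dilate the lesion (the smaller set) within its padded bbox only
  bb <- bbox_clip(bbox_expand(lesion$bbox, 1L), lesion$shape)
  les <- array(FALSE, dim = dim(shell$data))
  les[lesion$voxel_indices] <- TRUE
  les_sub <- bbox_extract(les, bb)
  shell_sub <- bbox_extract(shell_fg, bb)
  any(dilate26(les_sub) & shell_sub)
}

#' Classify one lesion by anatomical location
#'
#' Applies the stepwise cascade (see module header) to a lesion's
#' bounding-box centre against the lung-coordinate quartiles. A
#' "parenchymal" lesion with no overlap with the lung mask triggers a
#' warning, since the literal non-bordering rule cannot distinguish a deep
#' intrapulmonary nodule from a lesion far outside the lungs.
#'
#' @param lesion A [lesion_component()].
#' @param lung_mask Binary lung [label_mask()] on the same geometry.
#' @param quartiles Optional precomputed [lung_quartiles()].
#' @param shell Optional precomputed [lung_boundary_shell()].
#' @param strict_border Passed to [borders_lung_boundary()].
#' @return A `lesion_location` list: `category` (one of `"parenchymal"`,
#'   `"mediastinal"`, `"pleural"`), `rule_fired` (1, 2 or 3) and
#'   `center_used` (`(Xt, Yt, Zt)`, 0-based voxel coordinates).
#' @export
classify_lesion <- function(lesion, lung_mask, quartiles = NULL, shell = NULL,
                            strict_border = FALSE) {
  stopifnot(inherits(lesion, "lesion_component"), inherits(lung_mask, "label_mask"))
  if (!identical(as.integer(lesion$shape), as.integer(dim(lung_mask$data))))
    stop("lesion and lung mask are on different geometries")
  if (is.null(quartiles)) quartiles <- lung_quartiles(lung_mask)
  if (is.null(shell)) shell <- lung_boundary_shell(lung_mask)
  ctr <- bbox_center(lesion$bbox)
  if (!borders_lung_boundary(lesion, shell, strict = strict_border)) {
    if (!any(lung_mask$data[lesion$voxel_indices] != 0L))
      warning(sprintf("component %d labelled parenchymal but has no overlap with the lung mask",
                      lesion$component_id))
    loc <- list(category = "parenchymal", rule_fired = 1L, center_used = ctr)
  } else if (quartiles$x25 <= ctr[1] && ctr[1] <= quartiles$x75 &&
             ctr[2] <= quartiles$y75) {
    loc <- list(category = "mediastinal", rule_fired = 2L, center_used = ctr)
  } else {
    loc <- list(category = "pleural", rule_fired = 3L, center_used = ctr)
  }
  structure(loc, class = "lesion_location")
}

#' @export
print.lesion_location <- function(x, ...) {
  cat(sprintf("<lesion_location> %s (rule %d), centre (%.1f, %.1f, %.1f)\n",
              x$category, x$rule_fired, x$center_used[1], x$center_used[2],
              x$center_used[3]))
  invisible(x)
}

#' Classify every lesion of a ground-truth mask
#'
#' A binary mask is split into connected components; a multi-label mask is
#' split per label (each label = one tumour, even if labels touch).
#'
#' @param gt_mask Binary or multi-label [label_mask()].
#' @param lung_mask Binary lung [label_mask()], same geometry.
#' @param connectivity Component connectivity for binary masks; default 26.
#' @param strict_border Passed to [borders_lung_boundary()].
#' @return List of `list(component =, location =)` pairs, in component order.
#' @export
classify_all <- function(gt_mask, lung_mask, connectivity = 26,
                         strict_border = FALSE) {
  check_same_geometry(gt_mask, lung_mask, "ground truth/lung mask")
  comps <- if (max(gt_mask$data) > 1L) label_components(gt_mask)
           else connected_components(gt_mask, connectivity)
  if (length(comps) == 0L) return(list())
  q <- lung_quartiles(lung_mask)
  shell <- lung_boundary_shell(lung_mask)
  lapply(comps, function(cmp)
    list(component = cmp,
         location = classify_lesion(cmp, lung_mask, quartiles = q,
                                    shell = shell,
                                    strict_border = strict_border)))
}

#' Tabulate classifications
#'
#' @param classified Result of [classify_all()].
#' @param spacing Voxel spacing used for volumes.
#' @return `data.frame` with one row per lesion: `component_id`,
#'   `size_voxels`, `volume_cm3`, `Xt`, `Yt`, `Zt`, `category`, `rule_fired`.
#' @export
classification_table <- function(classified, spacing = voxel_spacing(1)) {
  v <- voxel_volume_cm3(spacing)
  rows <- lapply(classified, function(p) {
    ctr <- p$location$center_used
    data.frame(component_id = p$component$component_id,
               size_voxels = p$component$size,
               volume_cm3 = p$component$size * v,
               Xt = ctr[1], Yt = ctr[2], Zt = ctr[3],
               category = p$location$category,
               rule_fired = p$location$rule_fired)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
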