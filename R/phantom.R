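# Seeded synthetic thoracic phantom: two ellipsoidal lung fields separated
# by a mediastinal gap, lesions of the three anatomical categories with
# known ground-truth volumes, Gaussian intensity noise. Intensities are
# HU-like but arbitrary (the toolkit never interprets absolute HU): soft
# tissue ~ 40, lung ~ -700, lesion ~ 60. Lesions are placed so that their
# categories are unambiguous under the classification cascade:
#   parenchymal - sphere at least 2 voxels interior to a lung;
#   mediastinal - ellipsoid spanning the inter-lung gap, touching both inner
#                 lung surfaces, centre in the central X band and anterior
#                 of the lungs' y75;
#   pleural     - curvilinear spherical-shell cap hugging the outer lateral
#                 lung surface (the characteristic morphology of pleural
#                 metastases).

#' Specification of a synthetic thoracic phantom
#'
#' @param shape Volume shape in voxels; default `c(96, 96, 96)`.
#' @param spacing_mm Isotropic voxel edge, mm; default 2.
#' @param lung_centers Two rows (right, left lung) of 0-based voxel centres.
#' @param lung_semiaxes Two rows of per-axis ellipsoid semi-axes, voxels.
#' @param hu Named intensity means: `background`, `lung`, `lesion`.
#' @param noise_sd Gaussian intensity noise SD; default 4 (20% of the
#'   default lesion/soft-tissue contrast of 20).
#' @param lesions List of lesion specs, each a list with `category`
#'   (`"parenchymal"`, `"mediastinal"`, `"pleural"`) and geometry fields:
#'   spheres/ellipsoids take `center` (0-based voxels) and `radius_vox`;
#'   pleural caps take `thickness_vox`, `y_halfwidth_vox`, `z_halfheight_vox`
#'   and `side` (1 = right lung lateral surface, 2 = left). Optional
#'   `intensity` overrides `hu["lesion"]`.
#' @param translate Integer rigid translation (voxels) applied to the whole
#'   anatomy (lungs and lesions together).
#' @param seed Random seed; fixed seed gives byte-identical output.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 96L), spacing_mm = 2,
                         lung_centers = rbind(c(27, 48, 48), c(68, 48, 48)),
                         lung_semiaxes = rbind(c(15, 26, 34), c(15, 26, 34)),
                         hu = c(background = 40, lung = -700, lesion = 60),
                         noise_sd = 4,
                         lesions = default_phantom_lesions(),
                         translate = c(0L, 0L, 0L),
                         seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 8L), spacing_mm > 0,
            nrow(lung_centers) == 2L, nrow(lung_semiaxes) == 2L,
            noise_sd >= 0, length(translate) == 3L)
  structure(list(shape = as.integer(shape), spacing_mm = spacing_mm,
                 lung_centers = lung_centers, lung_semiaxes = lung_semiaxes,
                 hu = hu, noise_sd = noise_sd, lesions = lesions,
                 translate = as.integer(translate), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default three-lesion phantom layout
#'
#' One lesion per anatomical category: a parenchymal sphere in the right
#' lung, an anterior mediastinal ellipsoid bridging the inter-lung gap and
#' a curvilinear pleural cap on the right lateral lung surface.
#'
#' @return List of lesion specs for [phantom_spec()].
#' @export
default_phantom_lesions <- function() {
  list(
    list(category = "parenchymal", center = c(27, 48, 60), radius_vox = 6),
    list(category = "mediastinal", center = c(47.5, 38, 48),
         radius_vox = c(7, 8, 9)),
    list(category = "pleural", side = 1L, thickness_vox = 3,
         y_halfwidth_vox = 10, z_halfheight_vox = 12))
}

# 0-based coordinate arrays for a shape
coord_arrays <- function(shape) {
  arr <- array(0, dim = shape)
  list(x = slice.index(arr, 1) - 1, y = slice.index(arr, 2) - 1,
       z = slice.index(arr, 3) - 1)
}

ellipsoid_mask <- function(co, center, semi) {
  semi <- rep_len(semi, 3L)
  ((co$x - center[1]) / semi[1])^2 + ((co$y - center[2]) / semi[2])^2 +
    ((co$z - center[3]) / semi[3])^2 <= 1
}

erode6 <- function(fg, times = 1L) {
  for (t in seq_len(times)) {
    interior <- fg
    for (a in 1:3) for (dir in c(-1L, 1L))
      interior <- interior & shift_logical(fg, a, dir, fill = FALSE)
    fg <- interior
  }
  fg
}

carve_lesion <- function(les, co, lungs_fg, lung_centers, lung_semiaxes,
                         shape, index) {
  cat_ <- les$category
  if (cat_ == "parenchymal") {
    m <- ellipsoid_mask(co, les$center, les$radius_vox)
    if (!any(m)) stop(sprintf("lesion %d (parenchymal): empty at this size", index))
    if (any(m & !erode6(lungs_fg, 2L)))
      stop(sprintf("lesion %d (parenchymal): sphere of radius %.1f at (%s) is not >=2 voxels interior to a lung",
                   index, les$radius_vox[1], paste(les$center, collapse = ",")))
  } else if (cat_ == "mediastinal") {
    m <- ellipsoid_mask(co, les$center, les$radius_vox)
    if (!any(m)) stop(sprintf("lesion %d (mediastinal): empty at this size", index))
  } else if (cat_ == "pleural") {
    # pleural masses grow in the pleural space and indent the lung, so the
    # cap straddles the lung surface: `thickness_vox` inward, `outward_vox`
    # (default 1) outward -- curvilinear, bordering the lung boundary, and
    # almost entirely inside the lung bounding box
    side <- les$side %||% 1L
    c0 <- lung_centers[side, ]; semi <- lung_semiaxes[side, ]
    e <- ((co$x - c0[1]) / semi[1])^2 + ((co$y - c0[2]) / semi[2])^2 +
         ((co$z - c0[3]) / semi[3])^2
    tin <- les$thickness_vox / mean(semi)     # shell thickness in ellipsoid units
    tout <- (les$outward_vox %||% 1) / mean(semi)
    lateral <- if (side == 1L) co$x < c0[1] else co$x > c0[1]
    m <- e > (1 - tin)^2 & e <= (1 + tout)^2 & lateral &
      abs(co$y - c0[2]) <= les$y_halfwidth_vox &
      abs(co$z - c0[3]) <= les$z_halfheight_vox
    if (!any(m)) stop(sprintf("lesion %d (pleural): cap parameters produce no voxels", index))
  } else stop("unknown lesion category: ", cat_)
  m
}

#' Generate a synthetic thoracic phantom
#'
#' Deterministic given the spec's seed. The truth table records, per lesion,
#' the label, intended category, exact voxel count, volume in cm^3 and
#' bounding box -- the ground truth against which everything downstream is
#' scored.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_output`: `image` ([image_volume()]), `lung_mask`,
#'   `lesion_mask` (multi-label, one label per lesion), `truth`
#'   (`data.frame`) and the `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  shape <- spec$shape
  co <- coord_arrays(shape)
  tr <- spec$translate
  centers <- sweep(spec$lung_centers, 2, tr, `+`)
  lungA <- ellipsoid_mask(co, centers[1, ], spec$lung_semiaxes[1, ])
  lungB <- ellipsoid_mask(co, centers[2, ], spec$lung_semiaxes[2, ])
  if (any(lungA & lungB)) stop("lung ellipsoids overlap; widen the mediastinal gap")
  lungs <- lungA | lungB
  if (!any(lungs)) stop("lung ellipsoids lie outside the volume")

  lesion_lab <- array(0L, dim = shape)
  truth_rows <- list()
  v <- voxel_volume_cm3(voxel_spacing(spec$spacing_mm))
  for (i in seq_along(spec$lesions)) {
    les <- spec$lesions[[i]]
    if (!is.null(les$center)) les$center <- les$center + tr
    m <- carve_lesion(les, co, lungs, centers, spec$lung_semiaxes, shape, i)
    if (any(lesion_lab[m] != 0L))
      stop(sprintf("lesion %d overlaps an earlier lesion", i))
    lesion_lab[m] <- i
    idx <- which(m)
    coords <- arrayInd(idx, .dim = shape)
    truth_rows[[i]] <- data.frame(
      label = i, category = les$category, voxel_count = length(idx),
      volume_cm3 = length(idx) * v,
      bbox_lower_x = min(coords[, 1]) - 1L, bbox_upper_x = max(coords[, 1]),
      bbox_lower_y = min(coords[, 2]) - 1L, bbox_upper_y = max(coords[, 2]),
      bbox_lower_z = min(coords[, 3]) - 1L, bbox_upper_z = max(coords[, 3]))
  }
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(label = integer(0), category = character(0),
               voxel_count = integer(0), volume_cm3 = numeric(0))

  img <- array(spec$hu[["background"]], dim = shape)
  img[lungs] <- spec$hu[["lung"]]
  for (i in seq_along(spec$lesions)) {
    les <- spec$lesions[[i]]
    img[lesion_lab == i] <- les$intensity %||% spec$hu[["lesion"]]
  }
  if (spec$noise_sd > 0)
    img <- img + array(rnorm(prod(shape), 0, spec$noise_sd), dim = shape)

  sp <- voxel_spacing(spec$spacing_mm)
  structure(list(
    image = image_volume(img, spacing = sp),
    lung_mask = label_mask(lungs * 1L, spacing = sp),
    lesion_mask = label_mask(lesion_lab, spacing = sp),
    truth = truth, spec = spec),
    class = "phantom_output")
}

#' @export
print.phantom_output <- function(x, ...) {
  cat(sprintf("<phantom_output> %s voxels @ %g mm; %d lesion(s): %s\n",
              paste(x$spec$shape, collapse = "x"), x$spec$spacing_mm,
              nrow(x$truth), paste(x$truth$category, collapse = ", ")))
  invisible(x)
}

# Scale a lesion spec's size parameters by a volume growth factor.
grow_lesion_spec <- function(les, factor) {
  lin <- factor^(1 / 3)
  if (les$category %in% c("parenchymal", "mediastinal")) {
    les$radius_vox <- les$radius_vox * lin
  } else {
    # a cap grows in thickness and in angular extent
    les$thickness_vox <- les$thickness_vox * lin
    les$y_halfwidth_vox <- les$y_halfwidth_vox * lin
    les$z_halfheight_vox <- les$z_halfheight_vox * lin
  }
  les
}

jitter_lesion_spec <- function(les, size_jitter, pos_jitter) {
  f <- 1 + stats::runif(1, -size_jitter, size_jitter)
  les <- grow_lesion_spec(les, f^3)
  if (!is.null(les$center)) {
    dj <- sample(seq(-pos_jitter, pos_jitter), 3L, replace = TRUE)
    dj[1] <- 0   # keep the X placement so the intended category stays valid
    les$center <- les$center + dj
  }
  les
}

#' Generate a phantom cohort
#'
#' `n_scans` baseline scans (one synthetic patient each) with per-scan
#' jitter of lesion sizes/positions and a rigid integer translation of the
#' whole anatomy. With `growth_factor` set, each patient also gets a
#' follow-up scan in which every lesion's volume is grown by that factor
#' and the anatomy is translated again -- longitudinal pairs for testing
#' grid-cell reuse across scans.
#'
#' @param n_scans Number of baseline scans (>= 1).
#' @param base_spec A [phantom_spec()] template.
#' @param seed Cohort seed; per-scan seeds derive from it.
#' @param growth_factor Optional volumetric growth factor for follow-ups
#'   (e.g. 1.59).
#' @param size_jitter,pos_jitter Relative lesion size jitter and max
#'   positional jitter (voxels) per baseline scan.
#' @param max_translation Max |rigid translation| per axis, voxels.
#' @return A `phantom_cohort`: `scans` (named list of `phantom_output`s) and
#'   `manifest` (`data.frame`, one row per lesion per scan).
#' @export
generate_cohort <- function(n_scans, base_spec = phantom_spec(), seed = 1L,
                            growth_factor = NULL, size_jitter = 0.1,
                            pos_jitter = 2L, max_translation = 4L) {
  stopifnot(n_scans >= 1L)
  set.seed(seed)
  scans <- list(); rows <- list()
  for (p in seq_len(n_scans)) {
    patient_id <- sprintf("P%03d", p)
    lesions <- lapply(base_spec$lesions, jitter_lesion_spec,
                      size_jitter = size_jitter, pos_jitter = pos_jitter)
    tr0 <- sample(seq(-max_translation, max_translation), 3L, replace = TRUE)
    spec0 <- base_spec
    spec0$lesions <- lesions
    spec0$translate <- as.integer(tr0)
    spec0$seed <- as.integer((seed * 1000L + p * 10L) %% .Machine$integer.max)
    timepoints <- list(baseline = spec0)
    if (!is.null(growth_factor)) {
      spec1 <- spec0
      spec1$lesions <- lapply(lesions, grow_lesion_spec, factor = growth_factor)
      spec1$translate <- as.integer(tr0 +
        sample(seq(-max_translation, max_translation), 3L, replace = TRUE))
      spec1$seed <- spec0$seed + 1L
      timepoints$followup <- spec1
    }
    for (tp in names(timepoints)) {
      scan_id <- sprintf("%s-%s", patient_id, tp)
      ph <- generate_phantom(timepoints[[tp]])
      scans[[scan_id]] <- ph
      if (nrow(ph$truth) > 0L)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(patient_id = patient_id, scan_id = scan_id,
                     timepoint = tp), ph$truth)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
              else data.frame()
  structure(list(scans = scans, manifest = manifest, seed = seed),
            class = "phantom_cohort")
}

#' Reference threshold segmenter
#'
#' A deterministic stand-in for a learned segmenter, sufficient to exercise
#' the cropping and evaluation pipeline end to end: voxels at or above the
#' intensity threshold are tumour, connected components smaller than
#' `min_component_voxels` are discarded as specks.
#'
#' @param crop A `crop_region` with an image patch.
#' @param threshold Intensity threshold; default 50 (midway between the
#'   default soft-tissue and lesion means).
#' @param min_component_voxels Discard smaller components; default 5.
#' @param connectivity Speck-removal connectivity; default 26.
#' @return Binary integer array shaped like the crop.
#' @export
reference_segmenter <- function(crop, threshold = 50, min_component_voxels = 5L,
                                connectivity = 26) {
  stopifnot(inherits(crop, "crop_region"))
  patch <- crop$image_patch
  fg <- patch >= threshold
  if (!any(fg)) return(array(0L, dim = dim(patch)))
  lab <- label_components_cpp(fg, dim(patch), as.integer(connectivity))
  keep <- which(tabulate(lab[lab != 0L]) >= min_component_voxels)
  out <- array(0L, dim = dim(patch))
  out[lab %in% keep] <- 1L
  out
}
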