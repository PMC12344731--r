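# Segmentation evaluation: DSC at scan/crop/tumour level, absolute and
# relative volume difference, ground-truth/inference component matching
# (false positives are ignored for location-based summaries), per-location
# aggregation, rank-sum comparison of cropping strategies, and RECIST-style
# axial axis measurements.

fg_count <- function(x) {
  if (inherits(x, "label_mask")) x <- x$data
  sum(x != 0L)
}

fg_logical <- function(x) {
  if (inherits(x, "label_mask")) x <- x$data
  x != 0L
}

check_pair <- function(G, S) {
  if (inherits(G, "label_mask") && inherits(S, "label_mask"))
    check_same_geometry(G, S, "ground truth/inference")
  gl <- fg_logical(G); sl <- fg_logical(S)
  if (!identical(dim(gl), dim(sl)))
    stop(sprintf("geometry mismatch (ground truth/inference): shapes %s vs %s",
                 paste(dim(gl), collapse = "x"), paste(dim(sl), collapse = "x")))
  list(g = gl, s = sl)
}

#' Dice similarity coefficient
#'
#' `DSC(G, S) = 2|G n S| / (|G| + |S|)` where `|G|`, `|S|` count foreground
#' voxels and `|G n S|` the voxels foreground in both. Ranges from 0
#' (disjoint) to 1 (identical). Two empty masks agree that there is nothing,
#' so DSC is 1 by convention.
#'
#' @param G Ground-truth binary mask ([label_mask()] or array).
#' @param S Inference binary mask, same geometry.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(G, S) {
  p <- check_pair(G, S)
  ng <- sum(p$g); ns <- sum(p$s)
  if (ng + ns == 0L) return(1)
  2 * sum(p$g & p$s) / (ng + ns)
}

#' Absolute volume difference in cubic centimetres
#'
#' `AVD(G, S) = v * ||G| - |S||` with `v` the single-voxel volume in cm^3.
#' This compares foreground counts, not overlap: two disjoint masks of equal
#' volume have AVD 0.
#'
#' @inheritParams dsc
#' @param spacing [voxel_spacing()] (or object carrying one), mm.
#' @return AVD in cm^3, `>= 0`.
#' @export
avd <- function(G, S, spacing) {
  if (missing(spacing) && inherits(G, "label_mask")) spacing <- G$spacing
  p <- check_pair(G, S)
  voxel_volume_cm3(spacing) * abs(sum(p$g) - sum(p$s))
}

#' Relative volume difference
#'
#' `RVD(G, S) = ||G| - |S|| / |G|`, dimensionless and unbounded above (an
#' inference twice the true volume scores the same as a complete miss).
#' Undefined for an empty ground truth, which is an error rather than an
#' infinity, so undefined values cannot silently propagate into means.
#'
#' @inheritParams dsc
#' @return RVD `>= 0`.
#' @export
rvd <- function(G, S) {
  p <- check_pair(G, S)
  ng <- sum(p$g)
  if (ng == 0L) stop("RVD is undefined for an empty ground-truth mask")
  abs(ng - sum(p$s)) / ng
}

metric_record <- function(unit, unit_id, dsc, avd_cm3, rvd,
                          location = NA_character_,
                          crop_provenance = NA_character_) {
  data.frame(unit = unit, unit_id = as.character(unit_id), dsc = dsc,
              avd_cm3 = avd_cm3, rvd = rvd, location = location,
              crop_provenance = crop_provenance,
              stringsAsFactors = FALSE)
}

#' Scan-level metrics with pooled foreground
#'
#' All tumours are simultaneously treated as foreground: one DSC (plus AVD
#' and RVD) for the whole scan. Inference produced per crop must be
#' reassembled onto the scan canvas (see [paste_crop()]) first.
#'
#' @param gt_scan_mask Binary ground-truth [label_mask()] for the scan.
#' @param inference_scan_mask Binary inference mask, same geometry.
#' @param unit_id Identifier for the record; default `"scan"`.
#' @param crop_provenance Optional `"cell"` or `"box"` tag.
#' @return One-row `data.frame` (a metric record).
#' @export
scan_dsc <- function(gt_scan_mask, inference_scan_mask, unit_id = "scan",
                     crop_provenance = NA_character_) {
  d <- dsc(gt_scan_mask, inference_scan_mask)
  a <- avd(gt_scan_mask, inference_scan_mask, spacing_of(gt_scan_mask))
  r <- if (fg_count(gt_scan_mask) > 0L) rvd(gt_scan_mask, inference_scan_mask)
       else NA_real_
  metric_record("scan", unit_id, d, a, r, crop_provenance = crop_provenance)
}

#' Per-crop metrics
#'
#' Each cropped volume is a separate evaluation unit (a crop may contain
#' several tumours or portions of tumours). RVD is `NA` for crops with an
#' empty ground-truth patch.
#'
#' @param crops List of `list(gt =, pred =)` pairs of binary patches
#'   (arrays or patch-sized masks).
#' @param spacing [voxel_spacing()] of the parent scan.
#' @param provenance `"cell"` or `"box"`, recorded on every record.
#' @param unit_ids Optional identifiers, recycled from crop index.
#' @return `data.frame` of metric records, one row per crop.
#' @export
crop_metrics <- function(crops, spacing, provenance = NA_character_,
                         unit_ids = NULL) {
  if (length(crops) == 0L)
    return(metric_record(character(0), character(0), numeric(0), numeric(0),
                         numeric(0))[0, ])
  if (is.null(unit_ids)) unit_ids <- sprintf("crop%03d", seq_along(crops))
  rows <- lapply(seq_along(crops), function(i) {
    cr <- crops[[i]]
    if (is.null(cr$gt) || is.null(cr$pred))
      stop("each crop needs paired $gt and $pred patches (crop ", i, ")")
    d <- dsc(cr$gt, cr$pred)
    a <- voxel_volume_cm3(spacing) * abs(fg_count(cr$gt) - fg_count(cr$pred))
    r <- if (fg_count(cr$gt) > 0L)
      abs(fg_count(cr$gt) - fg_count(cr$pred)) / fg_count(cr$gt) else NA_real_
    metric_record("crop", unit_ids[i], d, a, r, crop_provenance = provenance)
  })
  do.call(rbind, rows)
}

#' Match inference components to ground-truth tumours
#'
#' Every inference connected component sharing at least one voxel with a
#' ground-truth tumour is attributed to that tumour (a component overlapping
#' several tumours is attributed, whole, to each of them). Components
#' overlapping no tumour are false positives; they are ignored by the
#' location-based (per-tumour) summaries but still penalize scan-level DSC.
#'
#' @param gt_tumors List of [lesion_component()]s (one per ground-truth
#'   tumour).
#' @param inference_mask Binary [label_mask()], same geometry.
#' @param connectivity Connectivity for inference components; default 26.
#' @return A `match_result`: `matches` (per tumour, integer ids of
#'   overlapping inference components), `inference_components`,
#'   `false_positive_ids`, `missed_gt` (tumour indices with no match) and
#'   `multi_matched_ids` (components attributed to more than one tumour).
#' @export
match_components <- function(gt_tumors, inference_mask, connectivity = 26) {
  stopifnot(inherits(inference_mask, "label_mask"))
  inf_comps <- connected_components(inference_mask, connectivity)
  shape <- dim(inference_mask$data)
  inf_label <- array(0L, dim = shape)
  for (c in inf_comps) inf_label[c$voxel_indices] <- c$component_id
  matches <- lapply(gt_tumors, function(g) {
    if (!identical(as.integer(g$shape), as.integer(shape)))
      stop("ground-truth tumour and inference mask are on different geometries")
    sort(unique(inf_label[g$voxel_indices][inf_label[g$voxel_indices] != 0L]))
  })
  matched_ids <- unlist(matches)
  all_ids <- vapply(inf_comps, `[[`, integer(1), "component_id")
  structure(list(
    matches = matches,
    gt_tumors = gt_tumors,
    inference_components = inf_comps,
    false_positive_ids = setdiff(all_ids, matched_ids),
    missed_gt = which(lengths(matches) == 0L),
    multi_matched_ids = sort(unique(matched_ids[duplicated(matched_ids)]))),
    class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d tumour(s): %d matched, %d missed; %d false-positive component(s)\n",
              length(x$matches), sum(lengths(x$matches) > 0L),
              length(x$missed_gt), length(x$false_positive_ids)))
  invisible(x)
}

#' Per-tumour metrics from a match result
#'
#' For each ground-truth tumour, `S` is the union of its matched inference
#' components and DSC/AVD/RVD are computed against that tumour's own
#' voxels. False-positive components never enter. Tumour-level summaries
#' average these records unweighted over tumours.
#'
#' @param match A [match_components()] result.
#' @param spacing [voxel_spacing()] of the scan.
#' @param locations Optional character vector of per-tumour locations.
#' @return `data.frame` of metric records, one row per ground-truth tumour.
#' @export
tumor_metrics <- function(match, spacing, locations = NULL) {
  stopifnot(inherits(match, "match_result"))
  comp_by_id <- match$inference_components
  ids <- vapply(comp_by_id, `[[`, integer(1), "component_id")
  rows <- lapply(seq_along(match$gt_tumors), function(t) {
    g <- match$gt_tumors[[t]]
    s_idx <- unlist(lapply(match$matches[[t]], function(id)
      comp_by_id[[which(ids == id)]]$voxel_indices))
    s_idx <- unique(s_idx)
    ng <- g$size; ns <- length(s_idx)
    ni <- length(intersect(g$voxel_indices, s_idx))
    d <- if (ng + ns == 0L) 1 else 2 * ni / (ng + ns)
    metric_record("tumor", sprintf("tumor%02d", t), d,
                  voxel_volume_cm3(spacing) * abs(ng - ns),
                  abs(ng - ns) / ng,
                  location = if (is.null(locations)) NA_character_
                             else locations[t])
  })
  do.call(rbind, rows)
}

#' Per-location summary of metric records
#'
#' Mean and SD of DSC, AVD and RVD keyed by location (plus an `"overall"`
#' row) and, when present, crop provenance. Locations with no records get
#' no row (absent, not zero-filled).
#'
#' @param records `data.frame` of metric records.
#' @return `data.frame` with columns `location`, `crop_provenance`, `n`,
#'   and mean/SD per metric.
#' @export
location_summary <- function(records) {
  empty <- data.frame(location = character(0), crop_provenance = character(0),
                      n = integer(0), dsc_mean = numeric(0), dsc_sd = numeric(0),
                      avd_mean = numeric(0), avd_sd = numeric(0),
                      rvd_mean = numeric(0), rvd_sd = numeric(0))
  if (is.null(records) || nrow(records) == 0L) return(empty)
  key <- ifelse(is.na(records$crop_provenance), "(none)",
                records$crop_provenance)
  rows <- list()
  for (pv in unique(key)) {
    sub <- records[key == pv, , drop = FALSE]
    groups <- c(list(overall = sub),
                split(sub, sub$location, drop = TRUE))
    for (g in names(groups)) {
      gr <- groups[[g]]
      if (nrow(gr) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        location = g, crop_provenance = pv, n = nrow(gr),
        dsc_mean = mean(gr$dsc), dsc_sd = sd(gr$dsc),
        avd_mean = mean(gr$avd_cm3), avd_sd = sd(gr$avd_cm3),
        rvd_mean = mean(gr$rvd, na.rm = TRUE),
        rvd_sd = sd(gr$rvd, na.rm = TRUE))
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Two-sided Mann-Whitney-Wilcoxon rank-sum test
#'
#' For combined sample sizes up to `exact_limit` the p-value is computed by
#' exact enumeration of all assignments of the pooled (mid-)ranks, which
#' remains valid under ties; larger samples use the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param a,b Non-empty numeric samples (e.g. per-crop DSCs under the two
#'   cropping strategies).
#' @param exact_limit Largest combined `n` for the exact branch; default 12.
#' @return List with `p_value`, `statistic` (Mann-Whitney U of `a`) and
#'   `method` (`"exact enumeration"` or `"normal approximation"`).
#' @export
rank_sum_test <- function(a, b, exact_limit = 12L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty")
  m <- length(a); n <- length(b); N <- m + n
  pooled <- c(a, b)
  r <- rank(pooled)                       # midranks under ties
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (N <= exact_limit) {
    sets <- combn(N, m)
    rank_sums <- colSums(matrix(r[sets], nrow = m))
    u_all <- rank_sums - m * (m + 1) / 2
    eps <- 1e-9
    p <- if (u_obs > m * n / 2) 2 * mean(u_all >= u_obs - eps)
         else 2 * mean(u_all <= u_obs + eps)
    p <- min(1, p)
    method <- "exact enumeration"
  } else {
    mu <- m * n / 2
    ties <- table(r)
    sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(p_value = 1, statistic = u_obs,
                                 method = "normal approximation"))
    z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(p_value = p, statistic = u_obs, method = method)
}

#' RECIST-style axial axis measurements of a lesion
#'
#' On each axial (constant-Z) slice through the lesion, the major axis is
#' the maximum pairwise physical distance between foreground voxel centres
#' and the minor axis is the maximum extent perpendicular to the realized
#' major-axis direction within the same slice. Returns the slice maximizing
#' the major axis (ties broken by the lowest slice index); the maximizing
#' point pair is the lexicographically first among ties, making the result
#' deterministic.
#'
#' @param lesion A [lesion_component()].
#' @param spacing [voxel_spacing()], mm.
#' @return List with `major_mm`, `minor_mm` and `slice_index` (0-based Z).
#' @export
axial_axis_measurements <- function(lesion, spacing) {
  stopifnot(inherits(lesion, "lesion_component"))
  s <- spacing_of(spacing)
  coords <- arrayInd(lesion$voxel_indices, .dim = lesion$shape) - 1L
  best <- list(major_mm = -1, minor_mm = 0, slice_index = NA_integer_)
  for (z in sort(unique(coords[, 3]))) {
    pts <- coords[coords[, 3] == z, 1:2, drop = FALSE]
    px <- pts[, 1] * s[1]; py <- pts[, 2] * s[2]
    n <- length(px)
    if (n == 1L) {
      major <- 0; minor <- 0
    } else {
      d2 <- outer(px, px, `-`)^2 + outer(py, py, `-`)^2
      maj2 <- max(d2)
      major <- sqrt(maj2)
      hit <- which(d2 == maj2, arr.ind = TRUE)
      hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
      hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
      if (maj2 == 0) {
        minor <- 0
      } else {
        u <- c(px[hit[2]] - px[hit[1]], py[hit[2]] - py[hit[1]])
        u <- u / sqrt(sum(u^2))
        perp <- c(-u[2], u[1])
        proj <- px * perp[1] + py * perp[2]
        minor <- max(proj) - min(proj)
      }
    }
    if (major > best$major_mm) {
      best <- list(major_mm = major, minor_mm = minor, slice_index = z)
    }
  }
  best
}
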