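# End-to-end evaluation: crop (cell and/or box), segment (pluggable),
# reassemble, match, score, summarize. Mirrors the clinical workflow: the
# physician picks regions (boxes around lesions, or grid cells stored for
# reuse), the segmenter runs per crop, and performance is reported at
# scan, crop and tumour level with per-location breakdowns.

#' Evaluate a segmenter on one scan
#'
#' Runs the full pipeline on in-memory objects. Ground-truth lesions are
#' taken per label (multi-label mask) or per connected component (binary
#' mask); each is anatomically classified; crops are built per strategy;
#' predictions come from a full-scan `inference` mask (cropped per region)
#' or from `segmenter` applied per crop; per-crop predictions are pasted
#' back onto the scan canvas (voxelwise OR) for scan-level scoring.
#'
#' @param image [image_volume()] of the scan.
#' @param lung_mask Binary lung [label_mask()], same geometry.
#' @param gt_mask Ground-truth lesion [label_mask()] (binary or one label
#'   per tumour), same geometry.
#' @param inference Optional full-scan binary inference [label_mask()]; when
#'   supplied, `segmenter` is not called.
#' @param segmenter Function of a `crop_region` returning a binary patch;
#'   default [reference_segmenter()].
#' @param strategies Subset of `c("cell", "box")`.
#' @param divisions,pad_fraction Lung-grid parameters.
#' @param margin_voxels Box-crop margin per side.
#' @param connectivity Component connectivity.
#' @param strict_border Passed to the location classifier.
#' @param scan_id Identifier used in the records.
#' @param segmenter_args Extra arguments for `segmenter`.
#' @return An `evaluation_report`: `records` (all metric rows), `summary`
#'   (per-location tumour-level table), `crop_summary`, `comparison`
#'   (cell-vs-box rank-sum on per-crop DSC, when both strategies ran),
#'   `classifications`, `counts` (false positives / missed per strategy)
#'   and a `provenance` block recording the conventions used.
#' @export
evaluate_segmentation <- function(image, lung_mask, gt_mask,
                                  inference = NULL,
                                  segmenter = reference_segmenter,
                                  strategies = c("cell", "box"),
                                  divisions = 5L, pad_fraction = 0,
                                  margin_voxels = 2L, connectivity = 26,
                                  strict_border = FALSE, scan_id = "scan",
                                  segmenter_args = list()) {
  strategies <- match.arg(strategies, c("cell", "box"), several.ok = TRUE)
  check_same_geometry(image, lung_mask, "image/lung mask")
  check_same_geometry(image, gt_mask, "image/ground truth")
  if (!is.null(inference)) check_same_geometry(image, inference, "image/inference")
  spacing <- spacing_of(image)
  gt_bin <- as_binary(gt_mask)

  gt_comps <- if (max(gt_mask$data) > 1L) label_components(gt_mask)
              else connected_components(gt_mask, connectivity)
  if (length(gt_comps) == 0L) stop("ground-truth mask contains no lesions")
  quart <- lung_quartiles(lung_mask)
  shell <- lung_boundary_shell(lung_mask)
  locations <- vapply(gt_comps, function(cmp)
    classify_lesion(cmp, lung_mask, quartiles = quart, shell = shell,
                    strict_border = strict_border)$category, character(1))

  grid <- build_lung_grid(lung_mask, divisions = divisions,
                          pad_fraction = pad_fraction)

  predict_patch <- function(crop) {
    if (!is.null(inference)) return(bbox_extract(inference$data, crop$bbox))
    do.call(segmenter, c(list(crop), segmenter_args))
  }

  records <- list(); counts <- list(); assembled <- list()
  for (strat in strategies) {
    crops <- if (strat == "box") {
      lapply(gt_comps, function(cmp)
        box_crop(image, cmp$bbox, margin_voxels = margin_voxels, mask = gt_bin))
    } else {
      cells <- cells_containing_mask(grid, gt_bin)
      lapply(cells, function(cl) cell_crop(image, grid, cl, mask = gt_bin))
    }
    if (length(crops) == 0L) stop("no ", strat, " crops could be built")
    preds <- lapply(crops, predict_patch)

    pairs <- Map(function(cr, pr) list(gt = cr$mask_patch, pred = pr),
                 crops, preds)
    crop_ids <- vapply(seq_along(crops), function(i) {
      pv <- crops[[i]]$provenance
      if (pv$type == "cell") sprintf("%s/%s", scan_id, pv$cell$label)
      else sprintf("%s/box%02d", scan_id, i)
    }, character(1))
    records[[paste0(strat, "_crop")]] <-
      crop_metrics(pairs, spacing, provenance = strat, unit_ids = crop_ids)

    scan_pred <- label_mask(array(0L, dim = dim(image$data)), spacing = spacing)
    for (i in seq_along(crops))
      scan_pred <- paste_crop(preds[[i]], crops[[i]]$bbox, scan_pred)
    assembled[[strat]] <- scan_pred
    rec <- scan_dsc(gt_bin, scan_pred, unit_id = scan_id,
                    crop_provenance = strat)
    records[[paste0(strat, "_scan")]] <- rec

    match <- match_components(gt_comps, scan_pred, connectivity)
    tm <- tumor_metrics(match, spacing, locations = locations)
    tm$crop_provenance <- strat
    tm$unit_id <- sprintf("%s/%s", scan_id, tm$unit_id)
    records[[paste0(strat, "_tumor")]] <- tm
    counts[[strat]] <- list(false_positives = length(match$false_positive_ids),
                            missed = length(match$missed_gt),
                            multi_matched = length(match$multi_matched_ids))
  }
  records <- do.call(rbind, c(unname(records), list(make.row.names = FALSE)))

  comparison <- NULL
  if (all(c("cell", "box") %in% strategies)) {
    cc <- records[records$unit == "crop" & records$crop_provenance == "cell", "dsc"]
    bc <- records[records$unit == "crop" & records$crop_provenance == "box", "dsc"]
    rs <- rank_sum_test(cc, bc)
    comparison <- list(cell_mean = mean(cc), cell_sd = sd(cc),
                       box_mean = mean(bc), box_sd = sd(bc),
                       p_value = rs$p_value, method = rs$method)
  }

  structure(list(
    records = records,
    summary = location_summary(records[records$unit == "tumor", , drop = FALSE]),
    crop_summary = location_summary(records[records$unit == "crop", , drop = FALSE]),
    comparison = comparison,
    classifications = data.frame(
      tumor = seq_along(gt_comps),
      size_voxels = vapply(gt_comps, `[[`, integer(1), "size"),
      location = locations),
    counts = counts,
    assembled = assembled,
    provenance = list(
      orientation = TETVOL_ORIENTATION,
      percentile_method = quart$percentile_method,
      connectivity = connectivity,
      divisions = divisions, pad_fraction = pad_fraction,
      margin_voxels = margin_voxels, strict_border = strict_border,
      spacing_mm = as.numeric(spacing), scan_id = scan_id,
      package_version = as.character(utils::packageVersion("tetvol")))),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report %s> %d record(s)\n",
              x$provenance$scan_id, nrow(x$records)))
  for (strat in names(x$counts)) {
    sr <- x$records[x$records$unit == "scan" &
                    x$records$crop_provenance == strat, ]
    cat(sprintf("  %4s: scan DSC %.3f; FP %d, missed %d\n", strat,
                sr$dsc[1], x$counts[[strat]]$false_positives,
                x$counts[[strat]]$missed))
  }
  if (!is.null(x$comparison))
    cat(sprintf("  cell vs box per-crop DSC: %.2f (%.2f) vs %.2f (%.2f), p = %.3g (%s)\n",
                x$comparison$cell_mean, x$comparison$cell_sd,
                x$comparison$box_mean, x$comparison$box_sd,
                x$comparison$p_value, x$comparison$method))
  invisible(x)
}

#' Evaluate a segmenter over a phantom cohort
#'
#' Runs [evaluate_segmentation()] on every scan of a [generate_cohort()]
#' result and pools the records; the cell-vs-box comparison is recomputed
#' on the pooled per-crop DSCs.
#'
#' @param cohort A `phantom_cohort`.
#' @param ... Passed to [evaluate_segmentation()].
#' @return An `evaluation_report` with pooled records (no `assembled`
#'   masks).
#' @export
evaluate_cohort <- function(cohort, ...) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  reports <- lapply(names(cohort$scans), function(id) {
    ph <- cohort$scans[[id]]
    evaluate_segmentation(ph$image, ph$lung_mask, as_binary(ph$lesion_mask),
                          scan_id = id, ...)
  })
  records <- do.call(rbind, c(lapply(reports, `[[`, "records"),
                              list(make.row.names = FALSE)))
  comparison <- NULL
  cc <- records[records$unit == "crop" & records$crop_provenance == "cell", "dsc"]
  bc <- records[records$unit == "crop" & records$crop_provenance == "box", "dsc"]
  if (length(cc) && length(bc)) {
    rs <- rank_sum_test(cc, bc)
    comparison <- list(cell_mean = mean(cc), cell_sd = sd(cc),
                       box_mean = mean(bc), box_sd = sd(bc),
                       p_value = rs$p_value, method = rs$method)
  }
  counts <- list()
  for (strat in names(reports[[1]]$counts))
    counts[[strat]] <- list(
      false_positives = sum(vapply(reports, function(r)
        r$counts[[strat]]$false_positives, numeric(1))),
      missed = sum(vapply(reports, function(r)
        r$counts[[strat]]$missed, numeric(1))))
  structure(list(
    records = records,
    summary = location_summary(records[records$unit == "tumor", , drop = FALSE]),
    crop_summary = location_summary(records[records$unit == "crop", , drop = FALSE]),
    comparison = comparison, counts = counts,
    classifications = do.call(rbind, lapply(reports, `[[`, "classifications")),
    provenance = reports[[1]]$provenance),
    class = "evaluation_report")
}

#' Write an evaluation report to disk
#'
#' Emits `records.csv` (full precision, one row per evaluation unit),
#' `summary.json` (per-location tables, comparison, counts, provenance) and
#' `report.txt` (human-readable tables, mean (SD) to 2 decimals). The
#' summaries are exactly recomputable from the CSV. Nothing is written if
#' any output fails to serialize.
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "evaluation_report"))
  payload <- list(
    records_csv = report$records,
    summary = list(tumor_by_location = report$summary,
                   crop_by_provenance = report$crop_summary,
                   comparison = report$comparison,
                   counts = report$counts,
                   provenance = report$provenance))
  txt <- format_report_text(report)
  json <- jsonlite::toJSON(payload$summary, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, dataframe = "rows", na = "null")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("records.csv", "summary.json", "report.txt"))
  write.csv(report$records, paths[1], row.names = FALSE)
  writeLines(json, paths[2])
  writeLines(txt, paths[3])
  invisible(paths)
}

format_report_text <- function(report) {
  fmt <- function(m, s) sprintf("%.2f (%.2f)", m, ifelse(is.na(s), 0, s))
  lines <- c(sprintf("tetvol evaluation report -- scan %s",
                     report$provenance$scan_id),
             sprintf("orientation %s; connectivity %d; %d^3 grid; percentiles: %s",
                     report$provenance$orientation, report$provenance$connectivity,
                     report$provenance$divisions, report$provenance$percentile_method),
             "", "Per-tumour metrics by location [mean (SD)]:")
  s <- report$summary
  for (i in seq_len(nrow(s)))
    lines <- c(lines, sprintf("  %-12s %-5s n=%-3d DSC %s  AVD %s cm3  RVD %s",
                              s$location[i], s$crop_provenance[i], s$n[i],
                              fmt(s$dsc_mean[i], s$dsc_sd[i]),
                              fmt(s$avd_mean[i], s$avd_sd[i]),
                              fmt(s$rvd_mean[i], s$rvd_sd[i])))
  if (!is.null(report$comparison))
    lines <- c(lines, "", sprintf(
      "Cell vs box per-crop DSC: %s vs %s, two-sided rank-sum p = %.3g (%s)",
      fmt(report$comparison$cell_mean, report$comparison$cell_sd),
      fmt(report$comparison$box_mean, report$comparison$box_sd),
      report$comparison$p_value, report$comparison$method))
  for (strat in names(report$counts))
    lines <- c(lines, sprintf(
      "%s strategy: %d false-positive component(s) ignored at tumour level, %d tumour(s) missed",
      strat, report$counts[[strat]]$false_positives,
      report$counts[[strat]]$missed))
  lines
}

#' File-based evaluation entry point
#'
#' Reads NIfTI inputs named in a configuration list, runs
#' [evaluate_segmentation()] and writes the report. Geometry mismatches are
#' reported with the offending file names before anything is written.
#'
#' @param config List (or path to a JSON/YAML file readable by
#'   [jsonlite::read_json()]) with paths `image`, `lung_mask`, `gt_mask`,
#'   optional `inference`, `output_dir`, and any parameter of
#'   [evaluate_segmentation()] (`strategies`, `divisions`, `margin_voxels`,
#'   ...).
#' @return The `evaluation_report`, invisibly.
#' @export
run_evaluate <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  for (p in c("image", "lung_mask", "gt_mask"))
    if (is.null(config[[p]]) || !file.exists(config[[p]]))
      stop("config must name an existing '", p, "' file")
  image <- read_volume(config$image)
  lung <- read_mask(config$lung_mask)
  gt <- read_mask(config$gt_mask)
  for (nm in c("lung_mask", "gt_mask")) {
    m <- if (nm == "lung_mask") lung else gt
    ok <- try(check_same_geometry(image, m), silent = TRUE)
    if (inherits(ok, "try-error"))
      stop(sprintf("geometry mismatch between %s and %s: %s", config$image,
                   config[[nm]], attr(ok, "condition")$message))
  }
  inference <- if (!is.null(config$inference)) read_mask(config$inference)
  args <- config[intersect(names(config),
                           c("strategies", "divisions", "pad_fraction",
                             "margin_voxels", "connectivity", "strict_border",
                             "scan_id"))]
  report <- do.call(evaluate_segmentation,
                    c(list(image = image, lung_mask = lung, gt_mask = gt,
                           inference = inference), args))
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  invisible(report)
}

#' Longitudinal volume tracking with stored grid cells
#'
#' For each scan of a patient, applies the stored cell selection (grid
#' rebuilt on that scan's lungs), segments within the selected cells,
#' reassembles, and reports per-lesion volume and axial major/minor axes.
#' If no selection exists for the patient, `bootstrap_mask` (a lesion mask
#' on the first scan) is used to select cells via [cells_containing_mask()]
#' -- the manual initial selection of the clinical workflow -- and the
#' selection is saved for subsequent scans.
#'
#' @param scans Named list of `list(image =, lung_mask =, inference =)`
#'   per scan (inference optional), in chronological order.
#' @param patient_id Patient identifier in the store.
#' @param store_path JSON selection store path.
#' @param bootstrap_mask Optional lesion [label_mask()] on the first scan.
#' @param segmenter,segmenter_args Segmenter used when no inference mask is
#'   given; default [reference_segmenter()].
#' @param divisions,pad_fraction,connectivity Grid/component parameters.
#' @return `data.frame`: one row per lesion per scan with `scan_id`,
#'   `lesion`, `volume_cm3`, `major_mm`, `minor_mm`, `slice_index`.
#' @export
run_track <- function(scans, patient_id, store_path, bootstrap_mask = NULL,
                      segmenter = reference_segmenter, segmenter_args = list(),
                      divisions = 5L, pad_fraction = 0, connectivity = 26) {
  stopifnot(length(scans) >= 1L)
  if (is.null(names(scans)) || any(names(scans) == ""))
    names(scans) <- sprintf("scan%02d", seq_along(scans))
  record <- tryCatch(load_selection(patient_id, store_path), error = function(e) NULL)
  if (is.null(record)) {
    if (is.null(bootstrap_mask))
      stop("no stored selection for patient '", patient_id,
           "' and no bootstrap mask to select cells from")
    grid <- build_lung_grid(scans[[1]]$lung_mask, divisions, pad_fraction)
    cells <- cells_containing_mask(grid, as_binary(bootstrap_mask))
    if (length(cells) == 0L) stop("bootstrap mask selects no grid cells")
    record <- cell_selection_record(patient_id, cells, names(scans)[1])
    save_selection(record, store_path)
  }
  rows <- list()
  for (id in names(scans)) {
    sc <- scans[[id]]
    crops <- apply_selection(sc$lung_mask, record, sc$image,
                             divisions = divisions, pad_fraction = pad_fraction,
                             lesion_mask = sc$tracked_mask %||% NULL)
    spacing <- spacing_of(sc$image)
    canvas <- label_mask(array(0L, dim = dim(sc$image$data)), spacing = spacing)
    for (cr in crops) {
      patch <- if (!is.null(sc$inference)) bbox_extract(sc$inference$data, cr$bbox)
               else do.call(segmenter, c(list(cr), segmenter_args))
      canvas <- paste_crop(patch, cr$bbox, canvas)
    }
    comps <- connected_components(canvas, connectivity)
    if (length(comps) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = patient_id, scan_id = id, lesion = NA_integer_,
        volume_cm3 = 0, major_mm = NA_real_, minor_mm = NA_real_,
        slice_index = NA_integer_)
      next
    }
    for (cmp in comps) {
      ax <- axial_axis_measurements(cmp, spacing)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = patient_id, scan_id = id, lesion = cmp$component_id,
        volume_cm3 = cmp$size * voxel_volume_cm3(spacing),
        major_mm = ax$major_mm, minor_mm = ax$minor_mm,
        slice_index = ax$slice_index)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$scan_id), , drop = FALSE]
}
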