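# Persistent per-patient grid-cell selections. Cells picked on one scan are
# recorded and reused (by cell index, with the grid rebuilt on each new
# scan's lungs) for longitudinal follow-up. The store is a single JSON file:
# diffable, desk-scale, vendor-neutral.

SELECTION_SCHEMA_VERSION <- 1L

#' A patient's recorded grid-cell selection
#'
#' @param patient_id Opaque patient identifier.
#' @param cells Non-empty list of [grid_cell()]s (duplicates removed).
#' @param source_scan_id Identifier of the scan the selection was made on.
#' @param created Timestamp string; defaults to now (UTC).
#' @return A `cell_selection_record`.
#' @export
cell_selection_record <- function(patient_id, cells, source_scan_id,
                                  created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")) {
  if (inherits(cells, "grid_cell")) cells <- list(cells)
  if (length(cells) == 0L) stop("a selection record needs at least one cell")
  labels <- vapply(cells, function(c) c$label, character(1))
  cells <- cells[!duplicated(labels)]
  structure(list(patient_id = as.character(patient_id), cells = cells,
                 source_scan_id = as.character(source_scan_id),
                 created = created),
            class = "cell_selection_record")
}

#' @export
print.cell_selection_record <- function(x, ...) {
  cat(sprintf("<cell_selection_record %s> %d cells from scan %s: %s\n",
              x$patient_id, length(x$cells), x$source_scan_id,
              paste(vapply(x$cells, `[[`, character(1), "label"), collapse = " ")))
  invisible(x)
}

record_to_json <- function(record) {
  list(cells = lapply(record$cells, function(c) c(c$i, c$j, c$k)),
       source_scan_id = record$source_scan_id,
       created = record$created)
}

json_to_record <- function(patient_id, x, divisions = 5L) {
  cells <- lapply(x$cells, function(ijk) {
    ijk <- unlist(ijk)
    grid_cell(ijk[1], ijk[2], ijk[3], divisions = max(divisions, max(ijk) + 1L))
  })
  cell_selection_record(patient_id, cells, x$source_scan_id, created = x$created)
}

read_selection_store <- function(store_path) {
  if (!file.exists(store_path))
    return(list(schema_version = SELECTION_SCHEMA_VERSION, patients = list()))
  store <- jsonlite::read_json(store_path, simplifyVector = FALSE)
  if (is.null(store$patients)) store$patients <- list()
  store
}

#' Save a patient's cell selection
#'
#' A new save replaces the patient's active record; the previous active
#' record is appended to that patient's history.
#'
#' @param record A [cell_selection_record()].
#' @param store_path Path of the JSON selection store (created if absent).
#' @return Invisibly `store_path`.
#' @export
save_selection <- function(record, store_path) {
  stopifnot(inherits(record, "cell_selection_record"))
  store <- read_selection_store(store_path)
  pid <- record$patient_id
  entry <- store$patients[[pid]]
  history <- if (is.null(entry)) list() else entry$history
  if (!is.null(entry$active)) history <- c(history, list(entry$active))
  store$patients[[pid]] <- list(active = record_to_json(record),
                                history = history)
  store$schema_version <- SELECTION_SCHEMA_VERSION
  jsonlite::write_json(store, store_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(store_path)
}

#' Load a patient's active cell selection
#'
#' @param patient_id Patient identifier.
#' @param store_path JSON selection store.
#' @param history If `TRUE`, return the full list (active first, then
#'   superseded records, newest last).
#' @return A [cell_selection_record()], or a list of them with
#'   `history = TRUE`.
#' @export
load_selection <- function(patient_id, store_path, history = FALSE) {
  store <- read_selection_store(store_path)
  entry <- store$patients[[as.character(patient_id)]]
  if (is.null(entry) || is.null(entry$active))
    stop("no selection recorded for patient '", patient_id, "' in ", store_path)
  active <- json_to_record(patient_id, entry$active)
  if (!history) return(active)
  c(list(active), lapply(entry$history, function(h) json_to_record(patient_id, h)))
}

#' Apply a stored selection to a new scan
#'
#' Rebuilds the lung grid on the new scan's lung mask and crops the stored
#' cell indices. Cell indices, not physical coordinates, are reused: because
#' the grid is always relative to the lungs, the cells approximately retain
#' anatomical correspondence across a patient's scans without registration.
#'
#' @param new_scan_lung_mask Binary lung [label_mask()] of the new scan.
#' @param record A [cell_selection_record()].
#' @param image The new scan's [image_volume()].
#' @param divisions,pad_fraction Grid parameters (must match those used when
#'   the selection was made).
#' @param lesion_mask Optional lesion mask; if supplied, lesion voxels
#'   outside the union of the selected cells trigger a coverage warning
#'   (tumour growth beyond the stored cells).
#' @return List of cell `crop_region`s.
#' @export
apply_selection <- function(new_scan_lung_mask, record, image,
                            divisions = 5L, pad_fraction = 0,
                            lesion_mask = NULL) {
  stopifnot(inherits(record, "cell_selection_record"))
  grid <- build_lung_grid(new_scan_lung_mask, divisions = divisions,
                          pad_fraction = pad_fraction)
  crops <- lapply(record$cells, function(cell)
    cell_crop(image, grid, cell, mask = lesion_mask))
  if (!is.null(lesion_mask)) {
    covered <- array(FALSE, dim = dim(lesion_mask$data))
    for (cr in crops) {
      r <- bbox_index_ranges(cr$bbox)
      covered[r[[1]], r[[2]], r[[3]]] <- TRUE
    }
    outside <- sum(lesion_mask$data != 0L & !covered)
    if (outside > 0L)
      warning(sprintf("%d lesion voxel(s) fall outside the %d stored cell(s) for patient %s; consider reselecting cells",
                      outside, length(record$cells), record$patient_id))
  }
  crops
}
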