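cube_lung <- function(lo = 10L, hi = 60L, shape = c(70L, 70L, 70L)) {
  arr <- array(0L, dim = shape)
  arr[(lo + 1):hi, (lo + 1):hi, (lo + 1):hi] <- 1L  # 0-based bbox [lo, hi)
  label_mask(arr)
}

test_that("grid boundaries divide the lung bbox into equal intervals", {
  g <- build_lung_grid(cube_lung(), divisions = 5)
  for (a in 1:3) expect_equal(g$boundaries[[a]], seq(10, 60, by = 10))
  expect_equal(g$divisions^3, 125)

  g1 <- build_lung_grid(cube_lung(), divisions = 1)
  expect_equal(cell_bbox(g1, grid_cell(0, 0, 0, 1)),
               bbox3d(c(10, 10, 10), c(60, 60, 60)))
  expect_error(build_lung_grid(label_mask(array(0L, dim = c(5, 5, 5)))), "empty")
})

test_that("voxel-to-cell assignment is half-open with the last interval closed", {
  g <- build_lung_grid(cube_lung(), divisions = 5)
  # 0-based voxel (25,35,47) is R index (26,36,48)
  c1 <- cell_of_voxel(g, c(26, 36, 48))
  expect_equal(c(c1$i, c1$j, c1$k), c(1, 2, 3))
  expect_equal(c1$label, "X1-Y2-Z3")
  c2 <- cell_of_voxel(g, c(21, 11, 11))       # 0-based x = 20, on a boundary
  expect_equal(c2$i, 1L)
  c3 <- cell_of_voxel(g, c(60, 60, 60))       # 0-based (59,59,59), upper corner
  expect_equal(c(c3$i, c3$j, c3$k), c(4, 4, 4))
  expect_null(cell_of_voxel(g, c(5, 5, 5)))   # outside the lung bbox
  expect_null(cell_of_voxel(g, c(61, 61, 61)))
})

test_that("cell crops tile the lung bbox disjointly and cover its mask counts", {
  lung <- cube_lung(10L, 57L)   # span 47, not divisible by 5
  g <- build_lung_grid(lung, divisions = 5)
  covered <- array(0L, dim = dim(lung$data))
  for (i in 0:4) for (j in 0:4) for (k in 0:4) {
    bb <- cell_bbox(g, grid_cell(i, j, k))
    r <- lapply(1:3, function(a) (bb$lower[a] + 1):bb$upper[a])
    covered[r[[1]], r[[2]], r[[3]]] <- covered[r[[1]], r[[2]], r[[3]]] + 1L
  }
  inside <- array(FALSE, dim = dim(lung$data))
  inside[11:57, 11:57, 11:57] <- TRUE
  expect_true(all(covered[inside] == 1L))   # exactly once inside the bbox
  expect_true(all(covered[!inside] == 0L))  # never outside

  # mask foreground splits across cell crops without loss
  set.seed(4)
  lesion <- label_mask(array(as.integer(runif(70^3) < 0.01), dim = c(70, 70, 70)))
  img <- image_volume(array(0, dim = c(70, 70, 70)))
  tot <- 0L
  for (i in 0:4) for (j in 0:4) for (k in 0:4)
    tot <- tot + sum(cell_crop(img, g, grid_cell(i, j, k), mask = lesion)$mask_patch)
  expect_equal(tot, sum(lesion$data[inside]))
})

test_that("cells_containing_mask equals the per-voxel brute force", {
  for (seed in 1:10) {
    set.seed(seed)
    ph <- generate_phantom(small_phantom_spec(seed = seed))
    g <- build_lung_grid(ph$lung_mask, divisions = 5)
    lesion <- as_binary_mask(ph$lesion_mask)
    got <- vapply(cells_containing_mask(g, lesion), function(c) c$label, character(1))
    idx <- which(lesion$data != 0L)
    want <- unique(na.omit(vapply(idx, function(v) {
      cl <- cell_of_voxel(g, arrayInd(v, dim(lesion$data)))
      if (is.null(cl)) NA_character_ else cl$label
    }, character(1))))
    expect_setequal(got, want)
  }
})

test_that("a lesion straddling one X boundary selects two cells differing in i", {
  lung <- cube_lung()
  g <- build_lung_grid(lung, divisions = 5)
  arr <- array(0L, dim = dim(lung$data))
  arr[20:22, 31, 31] <- 1L   # 0-based x 19..21 crosses the boundary at 20
  cells <- cells_containing_mask(g, label_mask(arr))
  expect_length(cells, 2L)
  expect_equal(sort(vapply(cells, `[[`, integer(1), "i")), c(0L, 1L))
  expect_equal(unique(vapply(cells, `[[`, integer(1), "j")), 2L)

  outside <- array(0L, dim = dim(lung$data)); outside[2, 2, 2] <- 1L
  expect_warning(res <- cells_containing_mask(g, label_mask(outside)), "outside")
  expect_length(res, 0L)
})

test_that("box crops honour margins, clip at edges, and round-trip via paste", {
  img <- image_volume(array(seq_len(40^3), dim = c(40, 40, 40)))
  set.seed(11)
  mask <- random_mask(c(40, 40, 40), p = 0.002)
  mask$data[20, 20, 20] <- 1L
  comp <- connected_components(mask, 26)[[1]]

  cr0 <- box_crop(img, comp$bbox, margin_voxels = 0, mask = mask)
  expect_equal(cr0$bbox, comp$bbox)

  near_edge <- bbox3d(c(0, 0, 0), c(3, 3, 3))
  cr <- box_crop(img, near_edge, margin_voxels = 5)
  expect_equal(cr$bbox$lower, c(0L, 0L, 0L))  # clipped, no out-of-bounds
  expect_equal(cr$bbox$upper, c(8L, 8L, 8L))

  expect_error(box_crop(img, bbox3d(c(50, 50, 50), c(55, 55, 55)), 0), "outside")

  # crop-then-paste reproduces the mask restricted to the bbox
  pasted <- paste_crop(cr0$mask_patch, cr0$bbox, dim(img$data))
  ref <- array(0L, dim = dim(img$data))
  r <- lapply(1:3, function(a) (cr0$bbox$lower[a] + 1):cr0$bbox$upper[a])
  ref[r[[1]], r[[2]], r[[3]]] <- mask$data[r[[1]], r[[2]], r[[3]]]
  expect_identical(pasted$data, ref)
})

test_that("paste_crop ORs overlapping patches and validates placement", {
  shape <- c(10, 10, 10)
  empty <- paste_crop(array(0L, dim = c(2, 2, 2)), bbox3d(c(0, 0, 0), c(2, 2, 2)), shape)
  expect_true(all(empty$data == 0L))

  a <- array(0L, dim = c(3, 3, 3)); a[1, 1, 1] <- 1L
  b <- array(0L, dim = c(3, 3, 3)); b[3, 3, 3] <- 1L
  canvas <- paste_crop(a, bbox3d(c(2, 2, 2), c(5, 5, 5)), shape)
  canvas <- paste_crop(b, bbox3d(c(2, 2, 2), c(5, 5, 5)), canvas)
  expect_equal(sum(canvas$data), 2L)
  expect_equal(canvas$data[3, 3, 3], 1L)
  expect_equal(canvas$data[5, 5, 5], 1L)

  expect_error(paste_crop(a, bbox3d(c(8, 8, 8), c(11, 11, 11)), shape), "outside")
  expect_error(paste_crop(a, bbox3d(c(0, 0, 0), c(2, 2, 2)), shape), "shape")
})

test_that("the selection store round-trips, versions and keeps history", {
  store <- tempfile(fileext = ".json")
  rec1 <- cell_selection_record("pt-1", list(grid_cell(1, 2, 3), grid_cell(1, 2, 4)),
                                "scan-a", created = "2026-01-01T00:00:00Z")
  save_selection(rec1, store)
  got <- load_selection("pt-1", store)
  expect_equal(vapply(got$cells, `[[`, character(1), "label"),
               c("X1-Y2-Z3", "X1-Y2-Z4"))
  expect_equal(got$source_scan_id, "scan-a")

  rec2 <- cell_selection_record("pt-1", grid_cell(0, 0, 0), "scan-b")
  save_selection(rec2, store)
  expect_equal(load_selection("pt-1", store)$source_scan_id, "scan-b")
  hist <- load_selection("pt-1", store, history = TRUE)
  expect_length(hist, 2L)
  expect_equal(hist[[2]]$source_scan_id, "scan-a")

  expect_error(load_selection("pt-9", store), "no selection")
  js <- jsonlite::read_json(store)
  expect_equal(js$schema_version, 1L)
})

test_that("grid and stored cells follow a rigid translation of the anatomy", {
  base <- small_phantom_spec(seed = 21)
  ph0 <- generate_phantom(base)
  moved <- base; moved$translate <- c(3L, -2L, 4L)
  ph1 <- generate_phantom(moved)

  g0 <- build_lung_grid(ph0$lung_mask)
  g1 <- build_lung_grid(ph1$lung_mask)
  expect_equal(g1$lung_bbox$lower, g0$lung_bbox$lower + c(3L, -2L, 4L))
  for (a in 1:3)
    expect_equal(g1$boundaries[[a]], g0$boundaries[[a]] + c(3, -2, 4)[a])

  lesion0 <- as_binary_mask(ph0$lesion_mask)
  lesion1 <- as_binary_mask(ph1$lesion_mask)
  lab0 <- vapply(cells_containing_mask(g0, lesion0), `[[`, character(1), "label")
  lab1 <- vapply(cells_containing_mask(g1, lesion1), `[[`, character(1), "label")
  expect_setequal(lab0, lab1)

  # apply_selection reuses indices on the new grid and still covers the lesion
  rec <- cell_selection_record("pt", cells_containing_mask(g0, lesion0), "t0")
  crops <- apply_selection(ph1$lung_mask, rec, ph1$image)
  covered <- array(FALSE, dim = dim(lesion1$data))
  for (cr in crops) {
    r <- lapply(1:3, function(a) (cr$bbox$lower[a] + 1):cr$bbox$upper[a])
    covered[r[[1]], r[[2]], r[[3]]] <- TRUE
  }
  expect_true(all(covered[lesion1$data != 0L]))
})

test_that("a lesion grown beyond its stored cells triggers a coverage warning", {
  ph <- generate_phantom(small_phantom_spec(seed = 5))
  g <- build_lung_grid(ph$lung_mask)
  one_cell <- list(cells_containing_mask(g, as_binary_mask(ph$lesion_mask))[[1]])
  rec <- cell_selection_record("pt", one_cell, "t0")
  big <- ph$lung_mask  # whole lung as "lesion": certainly exceeds one cell
  expect_warning(
    crops <- apply_selection(ph$lung_mask, rec, ph$image, lesion_mask = big),
    "outside")
  expect_length(crops, 1L)
})
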