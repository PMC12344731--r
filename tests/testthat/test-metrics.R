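mk <- function(arr, sp = 1) label_mask(arr, spacing = voxel_spacing(sp))

test_that("dsc/avd/rvd satisfy their edge contracts", {
  a <- array(0L, dim = c(4, 4, 4)); a[1:8] <- 1L
  b <- array(0L, dim = c(4, 4, 4)); b[9:16] <- 1L
  half <- array(0L, dim = c(4, 4, 4)); half[5:12] <- 1L
  empty <- array(0L, dim = c(4, 4, 4))

  expect_equal(dsc(mk(a), mk(a)), 1)                       # identity
  expect_equal(dsc(mk(a), mk(b)), 0)                       # disjoint
  expect_equal(dsc(mk(empty), mk(empty)), 1)               # both empty
  expect_equal(dsc(mk(a), mk(half)), 0.5)                  # |G|=|S|=8, overlap 4
  expect_equal(dsc(mk(a), mk(b)), dsc(mk(b), mk(a)))       # symmetric

  g100 <- array(0L, dim = c(10, 10, 10)); g100[1:100] <- 1L
  s80 <- array(0L, dim = c(10, 10, 10)); s80[1:80] <- 1L
  expect_equal(avd(mk(g100), mk(s80)), 0.02)
  expect_equal(avd(mk(g100), mk(g100)), 0)
  expect_equal(avd(mk(a), mk(b)), 0)      # equal counts, disjoint: AVD is 0
  empty10 <- array(0L, dim = c(10, 10, 10))
  expect_equal(rvd(mk(g100), mk(s80)), 0.2)
  expect_equal(rvd(mk(g100), mk(empty10)), 1)
  s200 <- array(0L, dim = c(10, 10, 10)); s200[1:200] <- 1L
  expect_equal(rvd(mk(g100), mk(s200)), 1)  # overshoot = miss
  expect_error(rvd(mk(empty10), mk(g100)), "empty ground-truth")

  # avd scales with voxel volume; rvd does not
  expect_equal(avd(mk(g100, 2), mk(s80, 2)), 8 * 0.02)
  expect_equal(rvd(mk(g100, 2), mk(s80, 2)), rvd(mk(g100), mk(s80)))

  wrong <- mk(array(0L, dim = c(3, 3, 3)))
  expect_error(dsc(mk(a), wrong), "mismatch")
})

test_that("metrics equal the counting oracle on random mask pairs", {
  for (seed in 1:40) {
    set.seed(seed)
    shape <- sample(8:24, 3, replace = TRUE)
    G <- array(as.integer(runif(prod(shape)) < 0.3), dim = shape)
    S <- array(as.integer(runif(prod(shape)) < 0.3), dim = shape)
    sp <- voxel_spacing(0.5 + seed %% 3, 1, 2)
    expect_identical(dsc(mk(G), mk(S)), oracle_dsc(G, S))
    expect_identical(avd(G, S, sp), oracle_avd(G, S, voxel_volume_cm3(sp)))
    if (sum(G) > 0) expect_identical(rvd(mk(G), mk(S)), oracle_rvd(G, S))
  }
})

test_that("scan-level DSC pools all tumours as one foreground", {
  gt <- array(0L, dim = c(20, 20, 4))
  gt[2:5, 2:5, 2] <- 1L     # tumour 1: 16 voxels
  gt[10:13, 10:13, 2] <- 1L # tumour 2: 16 voxels
  pred <- gt; pred[10:13, 10:13, 2] <- 0L  # second tumour missed entirely
  rec <- scan_dsc(mk(gt), mk(pred))
  expect_equal(rec$dsc, 2 / 3)           # 2x/(2x+x)
  expect_equal(rec$unit, "scan")
  expect_equal(scan_dsc(mk(gt), mk(gt))$dsc, 1)
  expect_equal(rec$rvd, 0.5)
})

test_that("crop metrics score each crop separately and summarize per provenance", {
  p1 <- array(1L, dim = c(3, 3, 3))
  crops <- list(list(gt = p1, pred = p1),
                list(gt = p1, pred = array(0L, dim = c(3, 3, 3))))
  recs <- crop_metrics(crops, voxel_spacing(1), provenance = "box")
  expect_equal(recs$dsc, c(1, 0))
  expect_equal(mean(recs$dsc), 0.5)
  same <- crop_metrics(list(list(gt = p1, pred = p1), list(gt = p1, pred = p1)),
                       voxel_spacing(1), provenance = "cell")
  expect_equal(mean(same$dsc), 1); expect_equal(sd(same$dsc), 0)
  expect_error(crop_metrics(list(list(gt = p1)), voxel_spacing(1)), "paired")
})

test_that("component matching agrees with the all-pairs overlap oracle", {
  # hand-built: one matched pair, no FPs
  gt <- array(0L, dim = c(12, 12, 12)); gt[3:5, 3:5, 3:5] <- 1L
  inf <- array(0L, dim = c(12, 12, 12)); inf[4:6, 4:6, 4:6] <- 1L
  gtc <- connected_components(mk(gt))
  m <- match_components(gtc, mk(inf))
  expect_equal(lengths(m$matches), 1L)
  expect_length(m$false_positive_ids, 0L)

  m0 <- match_components(gtc, mk(array(0L, dim = c(12, 12, 12))))
  expect_equal(m0$missed_gt, 1L)
  expect_equal(tumor_metrics(m0, voxel_spacing(1))$dsc, 0)

  for (seed in 1:15) {
    set.seed(seed)
    G <- random_mask(c(14, 14, 14), p = 0.08)
    S <- random_mask(c(14, 14, 14), p = 0.08)
    gtc <- connected_components(G, 26)
    m <- match_components(gtc, S, 26)
    infc <- connected_components(S, 26)
    overlap <- function(a, b) length(intersect(a$voxel_indices, b$voxel_indices)) > 0
    for (t in seq_along(gtc)) {
      want <- which(vapply(infc, overlap, logical(1), a = gtc[[t]]))
      expect_setequal(m$matches[[t]],
                      vapply(infc[want], `[[`, integer(1), "component_id"))
    }
    want_fp <- vapply(infc, function(ic)
      !any(vapply(gtc, overlap, logical(1), b = ic)), logical(1))
    expect_setequal(m$false_positive_ids,
                    vapply(infc[want_fp], `[[`, integer(1), "component_id"))
  }
})

test_that("tumour metrics average unweighted and ignore false positives", {
  gt <- array(0L, dim = c(24, 24, 6))
  gt[2:5, 2:5, 2:3] <- 1L     # tumour A, 32 voxels
  gt[12:15, 12:15, 2:3] <- 1L # tumour B, 32 voxels
  inf <- gt
  inf[12:15, 12:15, 3] <- 0L  # half of B missing -> dsc 2*16/(32+16) = 2/3
  inf[20:22, 20:22, 5] <- 1L  # false-positive blob far from both
  gtc <- connected_components(mk(gt))
  m <- match_components(gtc, mk(inf))
  expect_length(m$false_positive_ids, 1L)
  tm <- tumor_metrics(m, voxel_spacing(1), locations = c("pleural", "mediastinal"))
  expect_equal(sort(tm$dsc), c(2 / 3, 1))
  expect_equal(mean(tm$dsc), (1 + 2 / 3) / 2)

  # the FP hurts scan-level DSC but not tumour-level records
  no_fp <- inf; no_fp[20:22, 20:22, 5] <- 0L
  tm_clean <- tumor_metrics(match_components(gtc, mk(no_fp)), voxel_spacing(1),
                            locations = c("pleural", "mediastinal"))
  expect_equal(tm$dsc, tm_clean$dsc)
  expect_lt(scan_dsc(mk(gt), mk(inf))$dsc, scan_dsc(mk(gt), mk(no_fp))$dsc)

  # a component overlapping two tumours is attributed whole to each
  bridge <- array(0L, dim = c(24, 24, 6)); bridge[2:15, 2:15, 2] <- 1L
  mb <- match_components(gtc, mk(bridge))
  expect_equal(mb$multi_matched_ids, 1L)
  tb <- tumor_metrics(mb, voxel_spacing(1))
  expect_equal(tb$avd_cm3[1], tb$avd_cm3[2])  # same S against equal-size tumours
})

test_that("pooled scan DSC never exceeds the best per-tumour DSC when S is inside G", {
  for (seed in 1:20) {
    set.seed(seed)
    G <- random_mask(c(12, 12, 12), p = 0.15)
    if (sum(G$data) == 0) next
    S <- G; drop <- which(S$data != 0L)
    S$data[sample(drop, ceiling(length(drop) / 2))] <- 0L
    gtc <- connected_components(G)
    tm <- tumor_metrics(match_components(gtc, S), voxel_spacing(1))
    expect_lte(scan_dsc(G, S)$dsc, max(tm$dsc) + 1e-12)
  }
})

test_that("location summaries match direct computation and omit empty rows", {
  recs <- rbind(
    crop_metrics(list(list(gt = array(1L, dim = c(2, 2, 2)),
                           pred = array(1L, dim = c(2, 2, 2)))), voxel_spacing(1)),
    NULL)
  recs <- recs[0, ]  # empty input -> empty table
  expect_equal(nrow(location_summary(recs)), 0L)

  hand <- data.frame(unit = "tumor", unit_id = sprintf("t%d", 1:5),
                     dsc = c(0.9, 0.8, 0.7, 0.6, 0.95),
                     avd_cm3 = c(1, 2, 3, 4, 0.5),
                     rvd = c(0.1, 0.2, 0.3, 0.4, 0.05),
                     location = c("pleural", "pleural", "mediastinal",
                                  "mediastinal", "pleural"),
                     crop_provenance = "box")
  s <- location_summary(hand)
  expect_setequal(s$location, c("overall", "pleural", "mediastinal"))
  pl <- s[s$location == "pleural", ]
  expect_equal(pl$dsc_mean, mean(c(0.9, 0.8, 0.95)))
  expect_equal(pl$avd_sd, sd(c(1, 2, 0.5)))
  ov <- s[s$location == "overall", ]
  expect_equal(ov$rvd_mean, mean(hand$rvd))
  expect_false("parenchymal" %in% s$location)

  # single-location input: overall equals that location's row
  one <- hand[hand$location == "pleural", ]
  s1 <- location_summary(one)
  ov1 <- s1[s1$location == "overall", -1]; rownames(ov1) <- NULL
  pl1 <- s1[s1$location == "pleural", -1]; rownames(pl1) <- NULL
  expect_equal(ov1, pl1)
})

test_that("rank-sum exact branch enumerates correctly, including ties", {
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$p_value, 0.1)
  expect_equal(rs$method, "exact enumeration")

  tied <- rank_sum_test(c(2, 2, 3), c(2, 2, 3))
  expect_equal(tied$p_value, 1, tolerance = 1e-9)

  for (seed in 1:25) {
    set.seed(seed)
    m <- sample(2:5, 1); n <- sample(2:5, 1)
    a <- sample(1:6, m, replace = TRUE); b <- sample(1:6, n, replace = TRUE)
    expect_equal(rank_sum_test(a, b)$p_value, oracle_ranksum_p(a, b))
  }

  # without ties the exact branch agrees with the reference implementation
  for (seed in 1:10) {
    set.seed(seed + 100)
    a <- sample(1:100, 4); b <- sample(101:200, 5) - 100.5
    expect_equal(rank_sum_test(a, b)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value)
  }
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("large-sample branch tracks exact enumeration at n = 6 + 6", {
  set.seed(77)
  for (r in 1:5) {
    a <- rnorm(6); b <- rnorm(6, mean = 1)
    approx <- rank_sum_test(a, b, exact_limit = 0L)
    exact <- rank_sum_test(a, b)$p_value
    expect_equal(approx$method, "normal approximation")
    expect_lt(abs(approx$p_value - exact), 0.05)
    expect_equal(approx$p_value,
                 suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE)$p.value))
  }
})

test_that("axial axis measurements match hand cases and the all-pairs oracle", {
  single <- array(0L, dim = c(5, 5, 5)); single[3, 3, 3] <- 1L
  cmp <- connected_components(mk(single))[[1]]
  ax <- axial_axis_measurements(cmp, voxel_spacing(1))
  expect_equal(c(ax$major_mm, ax$minor_mm), c(0, 0))
  expect_equal(ax$slice_index, 2L)  # 0-based Z

  seg <- array(0L, dim = c(3, 13, 3)); seg[2, 2:12, 2] <- 1L  # 1x11 in-plane
  axs <- axial_axis_measurements(connected_components(mk(seg))[[1]], voxel_spacing(1))
  expect_equal(axs$major_mm, 10)
  expect_equal(axs$minor_mm, 0)

  for (seed in 1:30) {
    set.seed(seed)
    shape <- c(12, 12, 4)
    n <- sample(3:50, 1)
    idx <- sample(prod(shape), n)
    arr <- array(0L, dim = shape); arr[idx] <- 1L
    sp <- voxel_spacing(sample(c(0.5, 1, 2), 1), sample(c(0.5, 1), 1), 2)
    comp <- lesion_component(1L, which(arr != 0L), shape)
    got <- axial_axis_measurements(comp, sp)
    want <- oracle_axes(arrayInd(which(arr != 0L), shape) - 1L, sp)
    expect_equal(got$major_mm, want$major_mm)
    expect_equal(got$minor_mm, want$minor_mm)
    expect_equal(got$slice_index, want$slice_index)
  }
})
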