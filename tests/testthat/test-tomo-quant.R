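test_that("band segmentation reproduces ground-truth masks voxel-for-voxel", {
  tomo <- five_nucleoli_cell()
  seg <- segment_by_bands(tomo, ri_band("nucleolus", 1.356, 1.370))
  truth <- tomo$masks$nucleolus | tomo$masks$distractor
  expect_identical(seg$labels == 1L, truth)
})

test_that("band intervals are half-open: the upper bound is excluded", {
  v <- array(1.337, c(2, 2, 2))
  v[1, 1, 1] <- 1.370    # exactly hi
  v[2, 1, 1] <- 1.356    # exactly lo
  tomo <- ri_tomogram(v, rep(0.1, 3))
  seg <- segment_by_bands(tomo, ri_band("b", 1.356, 1.370))
  expect_identical(sum(seg$labels == 1L), 1L)
  expect_true(seg$labels[2, 1, 1] == 1L)
  expect_true(seg$labels[1, 1, 1] == 0L)
})

test_that("overlapping bands are resolved by list order", {
  v <- array(1.360, c(2, 2, 2))
  tomo <- ri_tomogram(v, rep(0.1, 3))
  seg <- segment_by_bands(tomo, list(ri_band("first", 1.355, 1.365),
                                     ri_band("second", 1.350, 1.370)))
  expect_true(all(seg$labels == 1L))
})

test_that("three narrow sub-bands isolate nested sub-nucleolar shells", {
  tomo <- shell_phantom()
  bands <- list(ri_band("low", 1.356, 1.368), ri_band("middle", 1.368, 1.380),
                ri_band("high", 1.380, 1.392))
  seg <- segment_by_bands(tomo, bands)
  expect_identical(seg$labels == 1L, tomo$masks$gc)
  expect_identical(seg$labels == 2L, tomo$masks$dfc)
  expect_identical(seg$labels == 3L, tomo$masks$fc)
})

test_that("segmentation is idempotent and volume-conserving", {
  tomo <- five_nucleoli_cell()
  bands <- list(ri_band("nucleolus", 1.356, 1.370),
                ri_band("cytoplasm", 1.343, 1.356))
  seg1 <- segment_by_bands(tomo, bands)
  seg2 <- segment_by_bands(tomo, bands)
  expect_identical(seg1$labels, seg2$labels)
  # per-component volumes sum to the band volume
  for (i in seq_along(bands)) {
    band_vol <- sum(seg1$labels == i) * prod(tomo$voxel_size)
    expect_equal(sum(seg1$components$volume_um3[seg1$components$band_index == i]),
                 band_vol)
  }
})

test_that("nucleolus detection applies the 2 um equivalent-diameter rule", {
  tomo <- five_nucleoli_cell()
  seg <- segment_by_bands(tomo, ri_band("nucleolus", 1.356, 1.370))
  det <- detect_nucleoli(seg)
  expect_identical(nrow(det), 5L)
  expect_true(all(det$equiv_diameter_um >= 2))
  expect_true(all(diff(det$volume_um3) <= 0))   # sorted by volume descending
  # filter disabled: the small distractor is counted too
  expect_identical(nrow(detect_nucleoli(seg, min_diameter = 0)), 6L)
  # empty band
  seg0 <- segment_by_bands(tomo, ri_band("nucleolus", 1.40, 1.41))
  expect_identical(nrow(detect_nucleoli(seg0)), 0L)
  expect_error(detect_nucleoli(seg, band = "missing"), "no band")
})

test_that("band-median RI is the midpoint of the rendering interval", {
  expect_equal(band_median_ri(ri_band("n", 1.358, 1.368)), 1.363)
  expect_equal(band_median_ri(ri_band("c", 1.344, 1.354)), 1.349)
  eps <- 1e-6
  expect_equal(band_median_ri(ri_band("d", 1.36, 1.36 + eps)), 1.36 + eps / 2)
  expect_error(ri_band("bad", 1.36, 1.35), "lo")
})

test_that("voxel-mean RI matches construction and bounds the band-median gap", {
  tomo <- sphere_phantom(r = 2, ri = 1.363)
  expect_identical(voxel_mean_ri(tomo, tomo$masks$sphere), 1.363)
  expect_error(voxel_mean_ri(tomo, array(FALSE, dim(tomo$values))), "empty")

  noisy <- sphere_phantom(r = 2, ri = 1.363, noise_sd = 0.001, seed = 3)
  m <- noisy$masks$sphere
  se <- 0.001 / sqrt(sum(m))
  expect_lt(abs(voxel_mean_ri(noisy, m) - 1.363), 3 * se)

  # estimator disagreement is bounded by half the band width
  band <- ri_band("nucleolus", 1.356, 1.370)
  seg <- segment_by_bands(noisy, band)
  gap <- abs(voxel_mean_ri(noisy, seg$labels == 1L) - band_median_ri(band))
  expect_lte(gap, (band$hi - band$lo) / 2)
})

test_that("volumes follow voxel count times voxel volume", {
  expect_equal(compute_volume(array(FALSE, c(2, 2, 2)), c(0.1, 0.1, 0.1)), 0)
  expect_equal(compute_volume(1L, c(0.356, 0.11, 0.11)), 0.0043076)
  tomo <- sphere_phantom(r = 2)
  vol <- compute_volume(tomo$masks$sphere, tomo$voxel_size)
  expect_lt(abs(vol - 33.510) / 33.510, 0.03)
})

test_that("percent change uses the earlier value as denominator", {
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(1.364, 1.376), 100 * 0.012 / 1.364)
  expect_equal(percent_change(1.348, 1.354), 100 * 0.006 / 1.348)
  # printed single-cell RI pairs: 0.88% and 0.45% on recomputation
  expect_equal(round(percent_change(1.364, 1.376), 2), 0.88)
  expect_equal(round(percent_change(1.348, 1.354), 2), 0.45)
  expect_error(percent_change(0, 1), "zero")
})

test_that("time-lapse summary tracks per-band RI and volume over frames", {
  ph <- function(n_ri, c_ri) nucleophys:::simple_cell_phantom(n_ri, c_ri)
  bands <- list(ri_band("nucleolus", 1.358, 1.385),
                ri_band("cytoplasm", 1.340, 1.358))

  # identical frames: all percent changes are zero
  same <- timelapse_summary(list(ph(1.364, 1.348), ph(1.364, 1.348)), bands)
  expect_true(all(same$changes$ri_pct_change == 0))
  expect_true(all(same$changes$volume_pct_change == 0))

  # ATP-depletion-style pair: nucleolar change ~2x the cytoplasmic change
  ts <- timelapse_summary(list(ph(1.364, 1.348), ph(1.376, 1.354)), bands,
                          interval_min = 20)
  expect_equal(round(ts$fold_ratio), 2)
  expect_equal(ts$changes$ri_before[ts$changes$band == "nucleolus"], 1.364)

  # monotone RI ramp gives monotone per-frame voxel-mean RI
  ramp <- lapply(seq(1.360, 1.372, length.out = 5), function(ri) ph(ri, 1.348))
  ts5 <- timelapse_summary(ramp, bands)
  nuc <- ts5$frames[ts5$frames$band == "nucleolus", ]
  expect_true(all(diff(nuc$voxel_mean_ri) > 0))

  expect_error(timelapse_summary(list(ph(1.364, 1.348)), bands), "2 time points")
})
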