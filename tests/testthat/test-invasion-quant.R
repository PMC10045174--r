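test_that("segmentation of a noiseless image recovers the truth mask exactly", {
  img <- generate_pulmosphere_image(40, 200, 60, noise_sd = 0, seed = 7)
  mask <- segment_foreground(img$pixels, "fixed", fixed_threshold = 0.1,
                             fill_holes = FALSE)
  expect_true(all(mask == img$invasion_mask))
  # pixel-count measurement then equals ground truth exactly
  expect_identical(measure_total_invaded_area(mask, "component_union"),
                   img$truth_H)
})

test_that("segmentation fails loudly on empty input", {
  blank <- matrix(0, 50, 50)
  expect_error(segment_foreground(blank, "fixed", fixed_threshold = 0.5),
               "empty foreground")
  speck <- blank; speck[25, 25] <- 1
  expect_error(segment_foreground(speck, "fixed", fixed_threshold = 0.5,
                                  min_size = 5),
               "empty foreground")
})

test_that("noisy segmentation overlaps ground truth at Jaccard >= 0.9", {
  for (seed in c(11, 12, 13, 14, 15)) {
    img <- generate_pulmosphere_image(40, 200, 60, noise_sd = 0.05,
                                      seed = seed)
    mask <- segment_foreground(img$pixels, "fixed", fixed_threshold = 0.15)
    jac <- sum(mask & img$invasion_mask) / sum(mask | img$invasion_mask)
    expect_gte(jac, 0.9)
  }
})

test_that("core area is exact on noiseless core-only disks", {
  for (r in c(12, 25, 40, 60)) {
    img <- generate_pulmosphere_image(r, 0, 0, noise_sd = 0, seed = 1)
    mask <- segment_foreground(img$pixels, "fixed", fixed_threshold = 0.1,
                               fill_holes = FALSE)
    expect_identical(as.integer(measure_core_area(mask)), img$truth_R)
    # hull of a disk is the disk itself, to within 1%
    hull <- measure_total_invaded_area(mask, "convex_hull")
    expect_lt(abs(hull / img$truth_R - 1), 0.01)
  }
})

test_that("core area stays within 2% when invading blobs are present", {
  for (seed in c(21, 22, 23, 24, 25)) {
    img <- generate_pulmosphere_image(40, 120, 60, noise_sd = 0, seed = seed)
    mask <- segment_foreground(img$pixels, "fixed", fixed_threshold = 0.1,
                               fill_holes = FALSE)
    R <- as.numeric(measure_core_area(mask))
    expect_lt(abs(R / img$truth_R - 1), 0.02)
  }
})

test_that("degenerate masks are rejected by the core measurement", {
  line <- matrix(0L, 40, 40); line[20, 5:35] <- 1L
  expect_error(measure_core_area(line, erosion_radius = 3), "annihilates")
  expect_error(measure_core_area(matrix(0L, 10, 10)), "nonempty")
})

test_that("convex hull H dominates the union and never shrinks with growth", {
  img <- generate_pulmosphere_image(30, 100, 40, noise_sd = 0, seed = 5)
  mask <- segment_foreground(img$pixels, "fixed", fixed_threshold = 0.1,
                             fill_holes = FALSE)
  h_hull <- measure_total_invaded_area(mask, "convex_hull")
  h_union <- measure_total_invaded_area(mask, "component_union")
  expect_gte(h_hull, h_union)
  # adding a pixel outside the hull can only grow H
  grown <- mask
  grown[2, 2] <- 1L
  expect_gte(measure_total_invaded_area(grown, "convex_hull"), h_hull)
  # adding pixels inside the hull leaves hull H unchanged
  inside <- mask
  inside[inside == 0 & row(inside) %in% 100:104 &
           col(inside) %in% 100:104] <- 1L
  expect_identical(measure_total_invaded_area(inside, "convex_hull"), h_hull)
})

test_that("quantify_image is deterministic and unit-invariant in ZOI%", {
  img <- generate_pulmosphere_image(30, 80, 40, noise_sd = 0.05, seed = 31)
  cfg_px <- run_config(threshold_method = "fixed", fixed_threshold = 0.15,
                       hull_method = "component_union")
  cfg_um <- run_config(threshold_method = "fixed", fixed_threshold = 0.15,
                       hull_method = "component_union", um_per_px = 0.65)
  a <- quantify_image(img, cfg_px, "P01", "untreated", 1)
  b <- quantify_image(img, cfg_px, "P01", "untreated", 1)
  expect_identical(a, b)
  m <- quantify_image(img, cfg_um, "P01", "untreated", 1)
  expect_identical(m$unit, "um^2")
  expect_equal(m$H, a$H * 0.65^2)
  # rescaling H and R together leaves the statistic unchanged
  expect_equal(m$zoi_percent, a$zoi_percent, tolerance = 1e-12)
})

test_that("end-to-end ZOI% recovery on a frozen synthetic batch is within 10%", {
  cfg <- run_config(threshold_method = "fixed", fixed_threshold = 0.15,
                    hull_method = "component_union")
  for (seed in 101:125) {
    img <- generate_pulmosphere_image(40, 200, 60, noise_sd = 0.05,
                                      seed = seed)
    q <- quantify_image(img, cfg, "P01", "untreated", 1)
    truth <- zoi_percent(img$truth_H, img$truth_R)
    expect_lt(abs(q$zoi_percent / truth - 1), 0.10)
  }
})

test_that("hull-based H tracks truth in a dense invasion regime", {
  # calibrated regime: invasion dense enough that the outer envelope and
  # the pixel union nearly coincide; frozen seeds
  for (seed in 1:5) {
    img <- generate_pulmosphere_image(40, 350, 12, noise_sd = 0, seed = seed)
    mask <- segment_foreground(img$pixels, "fixed", fixed_threshold = 0.1,
                               fill_holes = FALSE)
    H <- measure_total_invaded_area(mask, "convex_hull")
    expect_lt(abs(H / img$truth_H - 1), 0.05)
  }
})

test_that("stage failures are propagated with the stage name", {
  blank <- matrix(0, 64, 64)
  expect_error(quantify_image(blank, run_config(), "P01", "untreated", 1),
               "segment_foreground")
})
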