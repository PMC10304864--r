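test_that("scale calibration converts plate pixels to millimetres", {
  expect_equal(calibrate_scale(860), 0.1)
  expect_equal(calibrate_scale(86), 1.0)
  expect_error(calibrate_scale(0), "> 0")
  # rendered plate: the plate spans the image, so the scale is recoverable
  p <- generate_plate_image(c(2, 3), mm_per_px = 0.2, noise_sd = 0, seed = 1)
  recovered <- calibrate_scale(ncol(p$image$pixels))
  expect_lt(abs(recovered - 0.2) / 0.2, 0.01)
})

test_that("background subtraction flattens illumination but keeps plaques", {
  # flat image -> all zero
  flat <- matrix(120, 80, 80)
  expect_true(all(subtract_background(flat, 20) == 0))
  # radius larger than the image -> image minus its minimum
  grad <- matrix(seq(10, 60, length.out = 40), 40, 40, byrow = TRUE)
  out <- subtract_background(grad, 100)
  expect_equal(out, grad - min(grad), tolerance = 1e-8)
  # gradient with small bright disks: disks survive, gradient goes
  img <- matrix(seq(40, 90, length.out = 200), 200, 200, byrow = TRUE)
  mask1 <- disk_mask(200, 200, 60, 60, 5)
  mask2 <- disk_mask(200, 200, 140, 150, 5)
  img[mask1] <- img[mask1] + 80
  img[mask2] <- img[mask2] + 80
  sub <- subtract_background(img, 25)
  expect_lt(max(sub[!mask1 & !mask2]), 8)               # background gone
  expect_gt(min(sub[disk_mask(200, 200, 60, 60, 3)]), 80 * 0.9)  # contrast kept
  expect_error(subtract_background(img, 0), "> 0")
})

test_that("dual thresholding selects the band inside the elliptical ROI", {
  img <- plate_image(matrix(200, 100, 100), mm_per_px = 1,
                     roi_width_mm = 70, roi_height_mm = 70)
  mask <- apply_threshold(img)
  roi <- attr(mask, "roi")
  expect_true(all(mask[roi]))
  expect_false(any(mask[!roi]))
  img255 <- plate_image(matrix(255, 100, 100), mm_per_px = 1,
                        roi_width_mm = 70, roi_height_mm = 70)
  expect_false(any(apply_threshold(img255)))
  expect_error(apply_threshold(img, 200, 100), "lower threshold")
})

test_that("particle analysis measures disks and applies the printed filters", {
  mm <- 0.1
  # one disk of radius 1 mm (10 px)
  mask <- disk_mask(120, 120, 60, 60, 10)
  m <- analyze_particles(mask, mm)
  expect_equal(nrow(m), 1L)
  expect_equal(m$area_mm2, pi, tolerance = 0.05)
  expect_equal(m$equivalent_diameter_mm, 2, tolerance = 0.05)
  expect_gt(m$circularity, 0.9)
  expect_lte(m$circularity, 1)
  # disk of radius 0.2 mm: area 0.126 mm^2 < 0.2 -> filtered out
  small <- disk_mask(60, 60, 30, 30, 2)
  expect_equal(nrow(analyze_particles(small, mm)), 0L)
  # thin bar: circularity < 0.2 -> filtered out
  bar <- matrix(FALSE, 120, 120); bar[60:62, 10:110] <- TRUE
  expect_equal(nrow(analyze_particles(bar, mm)), 0L)
  # empty mask -> empty result
  expect_equal(nrow(analyze_particles(matrix(FALSE, 10, 10), mm)), 0L)
})

test_that("particle labeling is 8-connected", {
  mm <- 0.1
  # two disks joined only by a diagonal pixel chain: one component
  mask <- disk_mask(100, 100, 40, 40, 8) | disk_mask(100, 100, 57, 57, 8)
  mask[cbind(46:51, 46:51)] <- TRUE
  m <- analyze_particles(mask, mm, circularity_range = c(0, 1))
  expect_equal(nrow(m), 1L)
})

test_that("components touching the ROI boundary are discarded", {
  px <- matrix(0, 100, 100)
  img <- plate_image(px, mm_per_px = 1, roi_width_mm = 70, roi_height_mm = 70)
  roi <- phagevo:::roi_mask(img)
  # a disk clipped by the ROI edge and one safely interior
  img$pixels[disk_mask(100, 100, 50, 16, 5)] <- 200   # straddles ellipse edge
  img$pixels[disk_mask(100, 100, 50, 50, 5)] <- 200
  mask <- apply_threshold(img)
  m <- analyze_particles(mask, 0.2, area_range_mm2 = c(0.1, 64))
  expect_equal(nrow(m), 1L)
  expect_equal(m$centroid_x_mm, 50 * 0.2, tolerance = 0.05)
})

test_that("rendered plates are recovered by the full pipeline", {
  set.seed(1)
  diams <- runif(50, 0.6, 6)
  p <- generate_plate_image(diams, seed = 21)
  found <- plaque_pipeline(p$image, lower = 110, upper = 255)
  expect_gte(nrow(found), ceiling(0.95 * length(diams)))
  idx <- match_detections(p$truth, found)
  err <- abs(found$equivalent_diameter_mm[idx] - p$truth$diameter_mm)
  tol <- 0.05 * p$truth$diameter_mm + 2 * p$params$mm_per_px
  expect_true(all(err < tol))
})

test_that("measurements in mm are stable across render resolution", {
  diams <- c(1.5, 2.5, 3.5, 4.5)
  lo <- generate_plate_image(diams, mm_per_px = 0.2, noise_sd = 0,
                             illumination_gradient = 0, seed = 31)
  hi <- generate_plate_image(diams, mm_per_px = 0.1, noise_sd = 0,
                             illumination_gradient = 0, seed = 31)
  m_lo <- plaque_pipeline(lo$image, rolling_ball_radius_px = NA,
                          lower = 110, upper = 255)
  m_hi <- plaque_pipeline(hi$image, rolling_ball_radius_px = NA,
                          lower = 110, upper = 255)
  expect_equal(nrow(m_lo), length(diams))
  expect_equal(nrow(m_hi), length(diams))
  expect_lt(abs(mean(m_lo$equivalent_diameter_mm) -
                mean(m_hi$equivalent_diameter_mm)) /
              mean(m_hi$equivalent_diameter_mm), 0.02)
})

test_that("plaque size reports flag true diameter differences", {
  set.seed(3)
  big <- generate_plate_image(rnorm(150, 2.0, 0.15), seed = 41)
  small <- generate_plate_image(rnorm(150, 1.0, 0.15), seed = 42)
  m_big <- plaque_pipeline(big$image, lower = 110, upper = 255)
  m_small <- plaque_pipeline(small$image, lower = 110, upper = 255)
  meas <- rbind(data.frame(sample = "ancestor",
                           equivalent_diameter_mm = m_big$equivalent_diameter_mm),
                data.frame(sample = "evolved",
                           equivalent_diameter_mm = m_small$equivalent_diameter_mm))
  rep <- plaque_size_report(meas, reference = "ancestor")
  expect_true(rep$comparisons$significant[rep$comparisons$sample == "evolved"])
  expect_lt(rep$summary$mean_diameter_mm[rep$summary$sample == "evolved"],
            rep$summary$mean_diameter_mm[rep$summary$sample == "ancestor"])
  # a sample against itself is never significant
  self <- rbind(data.frame(sample = "a",
                           equivalent_diameter_mm = m_big$equivalent_diameter_mm),
                data.frame(sample = "b",
                           equivalent_diameter_mm = m_big$equivalent_diameter_mm))
  rep2 <- plaque_size_report(self, reference = "a")
  expect_false(any(rep2$comparisons$significant))
})
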