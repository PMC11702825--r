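mask_with_ez <- function(cols, width = 600L, height = 8L) {
  m <- matrix(0L, height, width)
  if (length(cols) > 0) m[4, cols] <- 1L
  m
}

test_that("per-B-scan EZ limits are the outer envelope of label-1 columns", {
  lims <- ez_limits(list(mask_with_ez(200:500),
                         mask_with_ez(integer(0)),
                         mask_with_ez(c(200:300, 400:500))),
                    positions_mm = c(-1, 0, 1))
  expect_equal(lims$left, c(200, NA, 200))
  expect_equal(lims$right, c(500, NA, 500))
})

test_that("interpolation bridges interior gaps but never extrapolates edges", {
  # constant limits across an absent middle scan
  lims <- ez_limits(list(mask_with_ez(100:200), mask_with_ez(integer(0)),
                         mask_with_ez(100:200)),
                    positions_mm = c(-0.011, 0, 0.011))
  map <- interpolate_limits(lims, n_columns = 600, lateral_um_per_px = 11)
  middle <- map$presence[which.min(abs(map$y_mm)), ]
  expect_equal(which(middle), 100:200)

  # linearly varying limits: midpoint scan gets the midpoint limits
  lims2 <- ez_limits(list(mask_with_ez(100:200), mask_with_ez(integer(0)),
                          mask_with_ez(200:300)),
                     positions_mm = c(-0.011, 0, 0.011))
  map2 <- interpolate_limits(lims2, 600, 11)
  mid2 <- map2$presence[which.min(abs(map2$y_mm)), ]
  expect_equal(range(which(mid2)), c(150, 250))

  # absent edge scans stay absent
  lims3 <- ez_limits(list(mask_with_ez(integer(0)), mask_with_ez(100:200),
                          mask_with_ez(100:200)),
                     positions_mm = c(-0.011, 0, 0.011))
  map3 <- interpolate_limits(lims3, 600, 11)
  expect_false(any(map3$presence[1, ]))

  # all absent -> empty map
  lims4 <- ez_limits(list(mask_with_ez(integer(0)), mask_with_ez(integer(0))),
                     positions_mm = c(0, 1))
  expect_false(any(interpolate_limits(lims4, 600, 11)$presence))

  # a single anchor emits a warning and no interpolation
  lims5 <- ez_limits(list(mask_with_ez(100:200), mask_with_ez(integer(0))),
                     positions_mm = c(0, 0.011))
  expect_warning(interpolate_limits(lims5, 600, 11), "only one")
})

test_that("EZ area counts present pixels times the 121 um^2 pixel", {
  # build a map directly: rectangle of 8264 pixels
  map <- structure(list(presence = matrix(FALSE, 100, 100),
                        y_mm = seq(0, by = 0.011, length.out = 100),
                        lateral_um_per_px = 11, row_pitch_um = 11,
                        pixel_area_um2 = 121), class = "enface_map")
  expect_equal(ez_area(map), 0)
  map$presence[1:88, 1:93] <- TRUE
  map$presence[89, 1:80] <- TRUE          # 88*93 + 80 = 8264
  expect_equal(sum(map$presence), 8264)
  expect_equal(ez_area(map), 8264 * 121e-6)
  # monotone: adding pixels never decreases area
  bigger <- map; bigger$presence[95, 5] <- TRUE
  expect_gt(ez_area(bigger), ez_area(map))
})

test_that("elliptical volume phantom recovers the analytic footprint area", {
  spec <- small_spec(width = 480L)
  spec$fovea_column <- 240L
  rx <- 1.2; ry <- 1.5
  vol <- generate_volume(spec, n_bscans = 61, footprint_mm = c(rx, ry),
                         span_mm = 4)
  lims <- ez_limits(vol$masks, vol$positions_mm)
  map <- interpolate_limits(lims, n_columns = 480, lateral_um_per_px = 11)
  area <- ez_area(map)
  expect_lt(abs(area - pi * rx * ry) / (pi * rx * ry), 0.02)
})

test_that("EZ width percent is the ROI-clipped extent over 6 mm", {
  # full-ROI EZ
  expect_equal(ez_width_percent(1, 600, fovea_column = 300,
                                lateral_um_per_px = 11), 100)
  # 3 mm centred on the fovea -> 50 %
  half_px <- 1.5 * 1000 / 11
  expect_equal(ez_width_percent(300 - half_px, 300 + half_px, 300, 11), 50,
               tolerance = 1e-6)
  expect_equal(ez_width_percent(NA, NA, 300, 11), 0)
})

test_that("ETDRS ROI masks have the right areas and sectors", {
  map <- structure(list(presence = matrix(FALSE, 620, 620),
                        y_mm = seq(-3.4, 3.4, length.out = 620),
                        lateral_um_per_px = 11, row_pitch_um = 11,
                        pixel_area_um2 = 121), class = "enface_map")
  map$row_pitch_um <- diff(map$y_mm[1:2]) * 1000
  map$pixel_area_um2 <- 11 * map$row_pitch_um
  roi_d <- etdrs_roi(map, fovea_column = 310, shape = "disc")
  area_d <- sum(roi_d$roi) * map$pixel_area_um2 * 1e-6
  expect_lt(abs(area_d - pi * 9) / (pi * 9), 0.01)
  roi_s <- etdrs_roi(map, fovea_column = 310, shape = "square")
  area_s <- sum(roi_s$roi) * map$pixel_area_um2 * 1e-6
  expect_lt(abs(area_s - 36) / 36, 0.01)
  # zero diameter -> empty
  expect_warning(
    roi0 <- etdrs_roi(map, 310, diameter_mm = 0, shape = "disc"), "clipped")
  expect_equal(sum(roi0$roi), 0)
  # sectors: centre label at the fovea, nasal side flips with laterality
  expect_equal(roi_d$sector[310, 310], "center")
  r_right <- etdrs_roi(map, 310, laterality = "right")
  r_left <- etdrs_roi(map, 310, laterality = "left")
  expect_equal(r_right$sector[310, 310 + 100], "inner_temporal")
  expect_equal(r_left$sector[310, 310 + 100], "inner_nasal")
})

test_that("enface_report ties the pieces together on a phantom volume", {
  spec <- small_spec(width = 480L)
  vol <- generate_volume(spec, n_bscans = 41, footprint_mm = c(1, 1),
                         span_mm = 4)
  rep <- enface_report(vol$masks, vol$positions_mm,
                       fovea_column = spec$fovea_column)
  expect_lt(abs(rep$area_mm2 - pi) / pi, 0.05)
  expect_equal(length(rep$width_percent), 41)
  mid <- rep$width_percent[21]
  expect_equal(mid, 100 * 2 / 6, tolerance = 0.02)
})
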