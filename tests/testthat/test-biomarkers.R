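test_that("layer bands reproduce the phantom geometry for all columns", {
  spec <- small_spec()
  out <- generate_bscan(spec, seed = 1)
  bands <- extract_layer_bands(out$mask)
  shift <- octez:::pit_shift(spec)
  expect_equal(unname(bands$upper["c1", ]), 41 + shift)
  expect_equal(unname(bands$lower["c1", ]), 43 + shift)
  expect_equal(unname(bands$upper["c2", ]), 26 + shift)
  expect_equal(unname(bands$lower["c4", ]), 51 + shift)

  # absent-label flagging
  m <- matrix(0L, 8, 3)
  m[3:5, 1] <- 1L
  b <- extract_layer_bands(m)
  expect_equal(unname(b$upper["c1", 1]), 3)
  expect_equal(unname(b$lower["c1", 1]), 5)
  expect_true(is.na(b$upper["c1", 2]))
})

test_that("peaks are band-interior maxima with ties to the inner row", {
  m <- matrix(0L, 16, 1)
  m[3:5, 1] <- 2L; m[7:8, 1] <- 3L; m[10:12, 1] <- 1L; m[14:15, 1] <- 4L
  img <- matrix(0, 16, 1)
  img[3:5, 1] <- c(0.2, 0.9, 0.4)   # OPL peak at row 4
  img[7:8, 1] <- c(0.9, 0.9)        # plateau -> row 7
  img[10:12, 1] <- c(0.1, 0.3, 0.8)
  img[14:15, 1] <- c(0.5, 0.6)
  pk <- locate_peaks(img, extract_layer_bands(m))
  expect_equal(pk$opl_row, 4)
  expect_equal(pk$opl_val, 0.9)
  expect_equal(pk$elm_row, 7)       # tie broken to smaller row
  expect_equal(pk$ez_row, 12)
  expect_equal(pk$bm_row, 15)       # outermost class-4 pixel
  expect_true(pk$valid)

  # noise-free phantom: peaks at band-centre rows (odd thicknesses)
  spec <- flat_spec()
  out <- generate_bscan(spec, seed = 1)
  pk2 <- locate_peaks(out$image, extract_layer_bands(out$mask))
  expect_true(all(pk2$ez_row == 42))    # 41..43 centre
  expect_true(all(pk2$opl_row == 28))   # 26..30 centre
  expect_true(all(pk2$valid))
})

test_that("weighted peak distances scale peak separations by Sy", {
  pk <- data.frame(column = 1:3,
                   opl_row = 60, opl_val = 0.5,
                   elm_row = 80, elm_val = 0.5,
                   ez_row = 100, ez_val = 0.8,
                   bm_row = 116, valid = TRUE)
  d <- weighted_peak_distances(pk, sy = 3.5)
  expect_equal(d$mean_um[d$measure == "opl_ez"], (100 - 60) * 3.5)   # 140
  expect_equal(d$mean_um[d$measure == "elm_ez"], 70)
  expect_equal(d$mean_um[d$measure == "bm_ez"], 56)
  expect_equal(d$mean_um[d$measure == "elm_bm"], 126)
  expect_true(all(d$sd_um == 0))
  expect_equal(d$n, rep(3L, 4))

  # additivity whenever ELM < EZ < BM, per column
  set.seed(4)
  pk2 <- data.frame(column = 1:50,
                    opl_row = sample(50:70, 50, TRUE), opl_val = 0.5,
                    elm_row = sample(80:90, 50, TRUE), elm_val = 0.5,
                    ez_row = sample(95:105, 50, TRUE), ez_val = 0.8,
                    bm_row = sample(110:120, 50, TRUE), valid = TRUE)
  d2 <- weighted_peak_distances(pk2, sy = 3.5)
  pc <- attr(d2, "per_column")
  expect_equal(pc$elm_bm, pc$elm_ez + pc$bm_ez)

  # degenerate: all peaks coincide
  pk3 <- pk; pk3$opl_row <- pk3$elm_row <- pk3$ez_row <- pk3$bm_row <- 10
  d3 <- weighted_peak_distances(pk3)
  expect_true(all(d3$mean_um == 0))

  # zero valid columns -> explicit undefined, not zero
  pk$valid <- FALSE
  d4 <- weighted_peak_distances(pk)
  expect_true(all(is.na(d4$mean_um)))
  expect_equal(d4$n, rep(0L, 4))
})

test_that("EZ thickness uses the inclusive pixel count times Sy", {
  m <- matrix(0L, 20, 4)
  m[6:10, 1:2] <- 1L   # 5 px
  m[6:11, 3:4] <- 1L   # 6 px
  b <- extract_layer_bands(m)
  expect_equal(ez_thickness(b, sy = 3.5)$mean_um, mean(c(17.5, 17.5, 21, 21)))
  m2 <- matrix(0L, 20, 1); m2[7, 1] <- 1L
  expect_equal(ez_thickness(extract_layer_bands(m2), 3.5)$mean_um, 3.5)
  m3 <- matrix(0L, 20, 2); m3[1:2, ] <- 2L
  th <- ez_thickness(extract_layer_bands(m3), 3.5)
  expect_true(is.na(th$mean_um))
  expect_equal(th$n, 0L)
  # mixed thicknesses: half 4 px, half 6 px -> mean of 14 and 21
  m4 <- matrix(0L, 20, 2); m4[6:9, 1] <- 1L; m4[6:11, 2] <- 1L
  expect_equal(ez_thickness(extract_layer_bands(m4), 3.5)$mean_um, 17.5)
})

test_that("rEZI is the signed EZ-OPL contrast relative to EZ, in percent", {
  pk <- data.frame(column = 1:4,
                   opl_row = 5, opl_val = 0.4,
                   elm_row = 8, elm_val = 0.5,
                   ez_row = 10, ez_val = 0.8,
                   bm_row = 12, valid = TRUE)
  expect_equal(rezi(pk)$percent, 50)                       # (0.8-0.4)/0.8
  pk$opl_val <- pk$ez_val
  expect_equal(rezi(pk)$percent, 0)
  pk$ez_val <- 0.5; pk$opl_val <- 0.6
  expect_equal(rezi(pk)$percent, -20)                      # sign preserved
  pk$ez_val[2] <- 0                                        # undefined ratio
  r <- rezi(pk)
  expect_equal(r$n, 3L)
  expect_equal(r$n_excluded, 1L)
})

test_that("phantom recovery: thickness, distances and rEZI are exact", {
  spec <- flat_spec()
  out <- generate_bscan(spec, seed = 1)
  bands <- extract_layer_bands(out$mask)
  peaks <- locate_peaks(out$image, bands)
  sy <- spec$axial_um_per_px
  expect_equal(ez_thickness(bands, sy)$mean_um, 3 * sy)
  d <- weighted_peak_distances(peaks, sy)
  expect_equal(d$mean_um[d$measure == "opl_ez"], (42 - 28) * sy)
  expect_equal(d$mean_um[d$measure == "elm_ez"], (42 - 37) * sy)
  expect_equal(d$mean_um[d$measure == "bm_ez"], (51 - 42) * sy)
  expect_equal(d$mean_um[d$measure == "elm_bm"], (51 - 37) * sy)
  expect_true(all(d$sd_um == 0))
  # rEZI from spec'd band reflectances: (0.85 - 0.55)/0.85
  expect_equal(rezi(peaks)$percent, 100 * (0.85 - 0.55) / 0.85)
  # micrometre outputs scale linearly with Sy
  expect_equal(weighted_peak_distances(peaks, 7)$mean_um, d$mean_um * 2)
  expect_equal(ez_thickness(bands, 7)$mean_um, 3 * 7)
})

test_that("EZ granularity equals the naive triple-loop oracle", {
  # 1-row EZ band alternating 0/1 across columns, beta = 1
  W <- 10
  px <- matrix(0, 4, W); px[2, ] <- rep(c(0, 1), 5)
  m <- matrix(0L, 4, W); m[2, ] <- 1L
  b <- extract_layer_bands(m)
  g <- ez_granularity(px, b, beta = 1, alpha = 0)
  o <- naive_granularity(px, b, beta = 1)
  expect_equal(g$lv, o$lv)
  expect_equal(g$tv_percent, o$tv_percent)
  # interior columns see two differing neighbours -> LV = 2
  expect_true(all(g$lv[2:9] == 2))

  # random EZ regions, all betas, against the oracle
  for (s in 1:6) {
    set.seed(s)
    px <- matrix(runif(100), 10, 10)
    m <- matrix(0L, 10, 10)
    rows <- sort(sample(1:10, 2))
    cols <- which(stats::runif(10) > 0.2)
    for (x in cols) m[rows[1]:rows[2], x] <- 1L
    b <- extract_layer_bands(m)
    for (beta in c(1, 3, 5, 7)) {
      g <- ez_granularity(px, b, beta = beta, alpha = 0)
      o <- naive_granularity(px, b, beta = beta)
      expect_equal(g$lv, o$lv, tolerance = 1e-12)
      expect_equal(g$tv_percent, o$tv_percent, tolerance = 1e-12)
    }
  }
  # constant EZ band -> zero local and total variation
  pc <- matrix(0.7, 6, 8)
  mc <- matrix(0L, 6, 8); mc[3:4, ] <- 1L
  gc <- ez_granularity(pc, extract_layer_bands(mc), beta = 3, alpha = 0)
  expect_true(all(gc$lv == 0))
  expect_equal(gc$tv_percent, 0)
  expect_error(ez_granularity(pc, extract_layer_bands(mc), beta = 2), "odd")
})

test_that("eccentricity sampling respects laterality and window geometry", {
  # constant signal: regional mean equals the constant
  vals <- rep(2.5, 200)
  r <- sample_at_eccentricity(vals, fovea_column = 100,
                              lateral_um_per_px = 11, laterality = "right")
  expect_equal(r$mean, c(2.5, 2.5))

  # linear ramp: mean of the symmetric window = value at +/- 0.5 mm
  ramp <- seq_len(200)
  r2 <- sample_at_eccentricity(ramp, 100, 11, "left")
  off <- 0.5 * 1000 / 11
  # left eye: nasal = right of fovea
  expect_equal(r2$mean[r2$region == "nasal"], mean(ramp[abs(seq_len(200) - (100 + off)) <= 0.1 * 1000 / 11]))
  expect_gt(r2$mean[r2$region == "nasal"], r2$mean[r2$region == "temporal"])

  # mirrored data between eyes swaps nasal/temporal
  set.seed(2)
  sig <- runif(201)
  rl <- sample_at_eccentricity(sig, 101, 11, "left")
  rr <- sample_at_eccentricity(rev(sig), 101, 11, "right")
  expect_equal(rl$mean[rl$region == "nasal"], rr$mean[rr$region == "nasal"])
  expect_equal(rl$mean[rl$region == "temporal"], rr$mean[rr$region == "temporal"])

  expect_error(sample_at_eccentricity(rep(1, 50), 25, 11, "right"),
               "outside the scan")
})

test_that("biomarker_record assembles full-scan and regional rows", {
  spec <- flat_spec(width = 160L)
  out <- generate_bscan(spec, seed = 1)
  rec <- biomarker_record(out$image, out$mask, alpha = 0, beta = 3)
  expect_setequal(unique(rec$region), c("full-scan", "nasal", "temporal"))
  full <- rec[rec$region == "full-scan", ]
  expect_equal(full$mean[full$measure == "ez_th"], 3 * 3.5)
  expect_equal(full$mean[full$measure == "rezi"],
               100 * (0.85 - 0.55) / 0.85)
  p <- attr(rec, "params")
  expect_equal(p$sy, 3.5)
  expect_true(is.finite(p$ez_tv_percent))
})
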