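test_that("phantom masks follow the spec geometry exactly, column by column", {
  spec <- small_spec()
  out <- generate_bscan(spec, seed = 1)
  expect_identical(dim(out$image$pixels), dim(out$mask))
  shift <- octez:::pit_shift(spec)
  for (x in c(1, 20, 32, 50, 64)) {
    ez_rows <- which(out$mask[, x] == 1L)
    expect_equal(ez_rows, (41L + shift[x]):(43L + shift[x]))
    opl_rows <- which(out$mask[, x] == 2L)
    expect_equal(length(opl_rows), 5L)
    expect_equal(min(opl_rows), 26L + shift[x])
  }
  # bands strictly ordered inner -> outer in every column
  for (x in seq_len(64)) {
    r <- function(k) range(which(out$mask[, x] == k))
    expect_true(r(2)[2] < r(3)[1] && r(3)[2] < r(1)[1] && r(1)[2] < r(4)[1])
  }
})

test_that("per-column EZ band height equals the spec thickness with no speckle", {
  spec <- small_spec()
  spec$bands$thickness[spec$bands$name == "ez"] <- 5L
  out <- generate_bscan(spec, seed = 1)
  heights <- colSums(out$mask == 1L)
  expect_true(all(heights == 5L))
})

test_that("ez_extent controls the lateral EZ footprint", {
  spec0 <- small_spec(ez_extent_mm = 0)
  expect_equal(sum(generate_bscan(spec0, seed = 1)$mask == 1L), 0L)
  spec1 <- small_spec(ez_extent_mm = 0.1)  # 0.1 mm / 11 um ~ 9 px half-width
  mask <- generate_bscan(spec1, seed = 1)$mask
  ez_cols <- which(colSums(mask == 1L) > 0)
  expect_true(all(abs(ez_cols - spec1$fovea_column) <= 0.1 * 1000 / 11))
  expect_true(length(ez_cols) >= 17)
})

test_that("identical spec and seed give bit-identical phantoms", {
  spec <- small_spec(speckle = 0.3)
  a <- generate_bscan(spec, seed = 7)
  b <- generate_bscan(spec, seed = 7)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$mask, b$mask)
  c <- generate_bscan(spec, seed = 8)
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("overlapping or overflowing band layouts are rejected", {
  expect_error(small_spec(height = 48L), "exceed|overlap")
  expect_error(phantom_spec(image_height = 64, image_width = 64,
                            opl_depth = 26, elm_depth = 28, ez_depth = 41,
                            rpe_depth = 47, pit_depth = 2), "overlap|ordered")
})

test_that("speckle is multiplicative, unit-mean, seeded, and clipped", {
  flat <- matrix(0.5, 80, 80)
  expect_identical(apply_speckle(flat, 0, seed = 1), flat)
  n1 <- apply_speckle(flat, 0.3, seed = 5)
  n2 <- apply_speckle(flat, 0.3, seed = 5)
  expect_identical(n1, n2)
  expect_true(all(n1 >= 0 & n1 <= 1))
  # Monte-Carlo unit-mean check on a bright constant region (no clipping
  # at 0.5 +/- 0.3*0.5): mean ratio within 3 standard errors of 1
  ratio <- n1 / flat
  se <- 0.3 / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - 1), 3 * se)
})

test_that("volume EZ extents follow the elliptical footprint", {
  spec <- small_spec(width = 120L)
  vol0 <- generate_volume(spec, n_bscans = 5, footprint_mm = 0)
  expect_true(all(vapply(vol0$masks, function(m) sum(m == 1L) == 0, logical(1))))

  # centre B-scan of an odd stack passes through the ellipse centre
  r <- 0.5
  vol <- generate_volume(spec, n_bscans = 7, footprint_mm = c(r, 2.5),
                         span_mm = 5)
  mid <- vol$masks[[4]]
  ez_cols <- which(colSums(mid == 1L) > 0)
  width_mm <- (max(ez_cols) - min(ez_cols) + 1) * spec$lateral_um_per_px / 1000
  expect_lt(abs(width_mm - 2 * r), spec$lateral_um_per_px / 1000 * 1.5)
  expect_equal(vol$images[[2]]$bscan_spacing_um, 5000 / 6)

  expect_error(generate_volume(spec, 1, c(1, 1)), "at least 2")
  expect_error(generate_volume(spec, 5, c(-1, 1)), "non-negative")
})
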