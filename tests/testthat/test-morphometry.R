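test_that("uniform flat cell matches the closed-form arithmetic", {
  # Delta n = 0.04, height 5 um, A = 100 um^2 (20x20 px at 0.5 um/px)
  px <- 0.5
  npx <- 30L
  mask <- matrix(0L, npx, npx)
  mask[6:25, 6:25] <- 1L
  ri <- matrix(1.333, npx, npx)
  ri[mask == 1L] <- 1.333 + 0.04
  hgt <- matrix(0, npx, npx)
  hgt[mask == 1L] <- 5
  fr <- field_frame(1L, mask, ri, hgt, pixel_size = px)
  rec <- extract_features(fr, morphometry_calibration(ri_increment = 0.19,
                                                      field_area = 236^2))
  expect_equal(rec$area, 100)
  expect_equal(rec$dry_mass, 0.04 * 5 * 100 / 0.19, tolerance = 1e-12)
  expect_equal(rec$volume, 500, tolerance = 1e-12)
  expect_equal(rec$dmd, 0.04 / 0.19, tolerance = 1e-12)
  expect_equal(rec$mean_ri, 1.373, tolerance = 1e-12)
  expect_equal(rec$extent, 1)                 # square fills its bbox
  expect_equal(rec$granularity, 10)           # uniform RI: no texture
})

test_that("rasterized disk recovers circle morphometry", {
  fr <- disk_frame(radius_um = 10, px = 0.5, npx = 61L)
  rec <- extract_features(fr)
  expect_equal(rec$area, pi * 100, tolerance = 0.02)
  expect_equal(rec$perimeter, 2 * pi * 10, tolerance = 0.05)
  expect_equal(rec$form_factor, 1, tolerance = 0.1)
  expect_lt(rec$eccentricity, 0.1)
  expect_equal(rec$extent, pi / 4, tolerance = 0.05)
  expect_lt(abs(rec$form_factor * rec$compactness - 1), 1e-12)
})

test_that("form factor times compactness is identically one", {
  for (s in 1:6) {
    rec <- extract_features(blob_frame(s))
    expect_lt(max(abs(rec$form_factor * rec$compactness - 1)), 1e-12)
    expect_true(all(rec$eccentricity >= 0 & rec$eccentricity < 1))
    expect_true(all(rec$extent > 0 & rec$extent <= 1))
  }
})

test_that("moment eccentricity matches a brute-force covariance oracle", {
  for (s in 1:20) {
    fr <- blob_frame(s)
    rec <- extract_features(fr)
    idx <- which(fr$label_mask == 1L, arr.ind = TRUE)
    S <- cov(idx) * (nrow(idx) - 1) / nrow(idx)   # population covariance
    ev <- sort(eigen(S, symmetric = TRUE)$values, decreasing = TRUE)
    ecc_bf <- sqrt(max(0, 1 - ev[2] / ev[1]))
    if (ecc_bf > 1e-6)
      expect_equal(rec$eccentricity, ecc_bf, tolerance = 1e-9)
  }
})

test_that("dry mass is additive under label splitting", {
  fr <- disk_frame(radius_um = 8, px = 0.5, npx = 61L)
  rec1 <- extract_features(fr)
  split_mask <- fr$label_mask
  cut_col <- 31L
  split_mask[, cut_col:ncol(split_mask)] <-
    2L * split_mask[, cut_col:ncol(split_mask)]
  fr2 <- field_frame(1L, split_mask, fr$ri_map, fr$height_map,
                     fr$pixel_size, fr$medium_index)
  rec2 <- extract_features(fr2)
  expect_equal(nrow(rec2), 2L)
  expect_equal(sum(rec2$dry_mass), rec1$dry_mass, tolerance = 1e-12)
  expect_equal(sum(rec2$volume), rec1$volume, tolerance = 1e-12)
  expect_equal(sum(rec2$area), rec1$area, tolerance = 1e-12)
})

test_that("morphometry is scale-equivariant under pixel refinement", {
  coarse <- disk_frame(radius_um = 10, px = 0.5, npx = 61L)
  fine <- disk_frame(radius_um = 10, px = 0.25, npx = 121L)
  rc <- extract_features(coarse, morphometry_calibration(pixel_size = 0.5))
  rf <- extract_features(fine, morphometry_calibration(pixel_size = 0.25))
  expect_equal(rf$area, rc$area, tolerance = 0.01)
  expect_equal(rf$perimeter, rc$perimeter, tolerance = 0.02)
  expect_equal(rf$dry_mass, rc$dry_mass, tolerance = 0.01)
})

test_that("degenerate labels and invalid maps are handled", {
  fr <- disk_frame(radius_um = 6, px = 0.5, npx = 41L)
  m <- fr$label_mask
  m[1, 1:3] <- 2L                      # 3-pixel object: sub-resolution
  fr2 <- field_frame(1L, m, fr$ri_map, fr$height_map, fr$pixel_size)
  expect_warning(rec <- extract_features(fr2), "fewer than 5")
  expect_equal(unique(rec$cell_id), "c001")
  bad_ri <- fr$ri_map
  bad_ri[fr$label_mask == 1L][5] <- 1.30
  expect_error(field_frame(1L, fr$label_mask, bad_ri, fr$height_map,
                           fr$pixel_size), "medium")
})

test_that("features_from_frames concatenates and validates geometry", {
  frames <- lapply(1:4, function(cy) {
    fr <- disk_frame(radius_um = 7, cycle = cy, npx = 41L)
    fr
  })
  rec <- features_from_frames(frames)
  expect_equal(nrow(rec), 4L)
  expect_equal(rec$cycle, 1:4)
  expect_equal(nrow(features_from_frames(list())), 0L)
  frames[[3]] <- disk_frame(radius_um = 7, cycle = 3L, npx = 45L)
  expect_error(features_from_frames(frames), "cycle 3")
})
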