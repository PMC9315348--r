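make_raw <- function(arr, wl = seq_len(dim(arr)[3]) * 10 + 900)
  hs_cube(arr, wl, stage = "raw")

test_that("median filter leaves constants alone and removes impulses", {
  cube <- make_raw(array(7, c(5, 5, 2)))
  expect_equal(median_filter_cube(cube)$values, array(7, c(5, 5, 2)))
  imp <- array(0, c(5, 5, 1))
  imp[3, 3, 1] <- 100
  expect_equal(median_filter_cube(make_raw(imp))$values[3, 3, 1], 0)
})

test_that("median filter matches a brute-force sorted-neighborhood oracle", {
  set.seed(11)
  arr <- array(rnorm(7 * 7 * 2), c(7, 7, 2))
  for (w in c(3L, 5L)) {
    got <- median_filter_cube(make_raw(arr), w)$values
    expect_equal(got, oracle_median_filter(arr, w))
  }
  expect_error(median_filter_cube(make_raw(arr), 4L), "odd")
  expect_error(median_filter_cube(hs_cube(arr, c(1000, 1100), "absorbance")),
               "stage")
})

frames_for <- function(d, white = 100, dark = 10) {
  list(white = array(white, c(1, d[2], d[3])),
       dark = array(dark, c(1, d[2], d[3])))
}

test_that("reflectance calibration is exact for known mixtures", {
  d <- c(4, 5, 3)
  fr <- frames_for(d)
  expect_equal(to_reflectance(make_raw(array(100, d)), fr$white, fr$dark)$values,
               array(1, d))
  r0 <- to_reflectance(make_raw(array(10, d)), fr$white, fr$dark)
  expect_equal(r0$values, array(1e-6, d))  # clipped from zero
  quarter <- to_reflectance(make_raw(array(10 + 0.25 * 90, d)), fr$white, fr$dark)
  expect_equal(quarter$values, array(0.25, d))
  expect_identical(quarter$stage, "reflectance")
})

test_that("nonpositive white-dark gaps are flagged, not clipped", {
  d <- c(3, 3, 2)
  fr <- frames_for(d)
  fr$white[1, 2, ] <- 5  # below dark
  refl <- to_reflectance(make_raw(array(50, d)), fr$white, fr$dark)
  expect_true(all(refl$meta$invalid_mask[, 2]))
  expect_false(any(refl$meta$invalid_mask[, -2]))
})

test_that("SNV standardizes each spectrum to mean 0, sd 1 (n-1 denominator)", {
  expect_equal(as.vector(snv(matrix(c(1, 2, 3), 1))), c(-1, 0, 1))
  set.seed(2)
  m <- matrix(rnorm(40 * 30, mean = 3, sd = 2), 40)
  s <- snv(m)
  expect_lt(max(abs(rowMeans(s))), 1e-10)
  expect_lt(max(abs(apply(s, 1, sd) - 1)), 1e-10)
  ## affine invariance
  expect_equal(snv(2 + 3 * m), s, ignore_attr = TRUE)
  ## constant spectra are flagged invalid, not divided
  m[5, ] <- 4
  s2 <- snv(m)
  expect_true(attr(s2, "invalid")[5])
  expect_true(all(is.na(s2[5, ])))
  expect_error(snv(matrix(1, 3, 1)), "2 bands")
})

test_that("background and saturated pixels are masked via PC1 thresholds", {
  cfg <- tiny_config(seed = 21)
  ph <- make_phantom_cube(cfg, position = 2)
  cube <- ph$cube
  cube$meta$detector_full_scale <- cfg$detector_full_scale
  ## inject saturated pixels
  sat <- rbind(c(20, 20), c(24, 25), c(30, 31))
  for (i in seq_len(nrow(sat)))
    cube$values[sat[i, 1], sat[i, 2], ] <- cfg$detector_full_scale
  refl <- to_reflectance(cube, ph$white_frame, ph$dark_frame)
  mask <- background_mask(snv(refl))
  bg <- ph$truth$tissue_mask == "background"
  expect_gte(mean(!mask[bg]), 0.99)            # background recall
  expect_gte(mean(mask[!bg]), 0.95)            # wood mostly retained
  expect_false(any(mask[sat]))                 # saturated flagged
  ## a homogeneous wood-only cube keeps every pixel (identical tissue
  ## chemistry, so PC1 scores are unimodal and within 4 robust SDs)
  cfg0 <- tiny_config(background_border = 0L, seed = 22,
                      decay_by_position = data.frame(
                        position = 1:7,
                        earlywood = seq(0.05, 0.95, length.out = 7),
                        latewood = seq(0.05, 0.95, length.out = 7)))
  ph0 <- make_phantom_cube(cfg0, position = 1)
  refl0 <- to_reflectance(ph0$cube, ph0$white_frame, ph0$dark_frame)
  expect_true(all(background_mask(snv(refl0))))
  ## absurd threshold errors out
  expect_error(background_mask(snv(refl0), k_sd = 1e-4), "retains")
})

test_that("ROI selection centers with floor tie-breaking and checks bounds", {
  big <- hs_cube(array(0, c(1029, 384, 1)), 1500, "raw")
  roi <- select_roi(big, 281, 301)
  expect_equal(unname(roi$offsets), c(374, 41))
  expect_equal(dim(roi$cube$values)[1:2], c(281L, 301L))
  small <- make_raw(array(rnorm(6 * 4 * 2), c(6, 4, 2)))
  expect_equal(select_roi(small, 6, 4)$cube$values, small$values)
  expect_error(select_roi(small, 7, 4), "at least")
  expect_error(select_roi(small, 2, 2, anchor = "explicit"), "explicit")
  got <- select_roi(small, 2, 2, row_offset = 1, col_offset = 2,
                    anchor = "explicit")
  expect_equal(got$cube$values, small$values[2:3, 3:4, , drop = FALSE])
})

test_that("absorbance conversion follows the log10 law", {
  d <- c(2, 2, 3)
  r <- hs_cube(array(1, d), c(1, 2, 3) * 100 + 900, "reflectance")
  expect_equal(to_absorbance(r)$values, array(0, d))
  r$values[] <- 0.1
  expect_equal(to_absorbance(r)$values, array(1, d))
  r$values[] <- 0.5
  expect_equal(to_absorbance(r)$values[1], log10(2), tolerance = 1e-12)
  r$values[1, 1, 1] <- 0
  expect_error(to_absorbance(r), "nonpositive")
  expect_error(to_absorbance(make_raw(array(1, d))), "stage")
})

test_that("band trimming is inclusive at both boundaries", {
  cube <- hs_cube(array(rnorm(2 * 2 * 4), c(2, 2, 4)),
                  c(1000, 1100, 2400, 2500), "absorbance")
  tr <- trim_bands(cube)
  expect_equal(tr$wavelengths, c(1100, 2400))
  full <- trim_bands(cube, 900, 2600)
  expect_equal(full$values, cube$values)
  expect_error(trim_bands(cube, 2700, 2600), "low must be")
  expect_error(trim_bands(cube, 2550, 2600), "retained")
  wl288 <- seq(930, 2550, length.out = 288)
  m <- matrix(rnorm(3 * 288), 3)
  got <- trim_bands(m, wavelengths = wl288)
  expect_equal(ncol(got), sum(wl288 >= 1100 & wl288 <= 2400))
})

test_that("average spectra equal the brute-force masked mean", {
  d <- c(6, 5, 4)
  wl <- seq_len(d[3]) * 100 + 1000
  arr <- array(2, d)
  cube <- hs_cube(arr, wl, "absorbance")
  same <- average_spectrum(cube)
  expect_equal(unname(same$values), rep(2, d[3]))
  expect_equal(same$n_pixels_averaged, 30)
  two <- array(0, c(1, 2, 3))
  two[1, 2, ] <- 2
  avg2 <- average_spectrum(hs_cube(two, c(1, 2, 3) * 100 + 1000, "absorbance"))
  expect_equal(unname(avg2$values), rep(1, 3))
  set.seed(4)
  arr <- array(rnorm(prod(d)), d)
  mask <- matrix(runif(d[1] * d[2]) > 0.4, d[1], d[2])
  got <- average_spectrum(hs_cube(arr, wl, "absorbance"), mask, "s1")
  manual <- sapply(seq_len(d[3]), function(b) mean(arr[, , b][mask]))
  expect_equal(unname(got$values), manual)
  expect_error(average_spectrum(cube, mask = matrix(FALSE, d[1], d[2])),
               "empty mask")
})

test_that("the preprocessing chain enforces stage ordering", {
  cfg <- noise_free_config()
  ph <- make_phantom_cube(cfg, position = 1)
  expect_error(snv(ph$cube), "stage")
  expect_error(to_absorbance(ph$cube), "stage")
  expect_error(to_reflectance(
    to_reflectance(ph$cube, ph$white_frame, ph$dark_frame),
    ph$white_frame, ph$dark_frame), "stage")
})
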