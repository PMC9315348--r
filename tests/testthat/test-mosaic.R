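snv_cube_from <- function(arr, wl = seq_len(dim(arr)[3]) * 100 + 1000)
  hs_cube(arr, wl, stage = "snv")

test_that("unfolding keeps every retained pixel once and centers columns", {
  set.seed(1)
  arr <- array(rnorm(4 * 3 * 5), c(4, 3, 5))
  mos <- build_mosaic(list(a = snv_cube_from(arr)))
  expect_equal(nrow(mos$spectra), 12)
  expect_lt(max(abs(colMeans(mos$spectra))), 1e-10)
  ## round trip through the index map restores the original pixels
  m <- sweep(mos$spectra, 2, -mos$center)
  rebuilt <- array(NA_real_, dim(arr))
  for (i in seq_len(nrow(mos$index_map)))
    rebuilt[mos$index_map$row[i], mos$index_map$col[i], ] <- m[i, ]
  expect_equal(rebuilt, arr)
  ## row-major pixel ordering
  expect_equal(mos$index_map$row[1:4], c(1, 1, 1, 2))
})

test_that("seven full-size ROIs unfold to the expected pixel count", {
  cubes <- replicate(7, snv_cube_from(array(0, c(281, 301, 2)),
                                      wl = c(1100, 1200)),
                     simplify = FALSE)
  mos <- build_mosaic(cubes)
  expect_equal(nrow(mos$spectra), 7 * 281 * 301)
  expect_equal(nrow(mos$spectra), 592067)
})

test_that("masks drop pixels and wavelength mismatches error", {
  arr <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  msk <- matrix(TRUE, 3, 3); msk[1, ] <- FALSE
  mos <- build_mosaic(list(a = snv_cube_from(arr)), masks = list(msk))
  expect_equal(nrow(mos$spectra), 6)
  expect_true(all(mos$index_map$row > 1))
  other <- snv_cube_from(arr, wl = c(1100, 1300))
  expect_error(build_mosaic(list(snv_cube_from(arr), other)), "wavelength")
})

test_that("mosaic PCA matches a brute-force covariance eigendecomposition", {
  set.seed(3)
  M <- matrix(rnorm(500 * 30), 500, 30)
  mos <- structure(list(spectra = sweep(M, 2, colMeans(M)),
                        center = colMeans(M),
                        index_map = data.frame(sample = "a", row = 1:500, col = 1),
                        layout = list(a = c(500L, 1L)),
                        wavelengths = seq_len(30) * 10 + 1000),
                   class = "mosaic")
  fit <- mosaic_pca(mos, 4)
  ev <- eigen(crossprod(mos$spectra), symmetric = TRUE)
  for (j in 1:4) {
    v <- ev$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_lt(max(abs(fit$loadings[, j] - v)), 1e-8)
  }
  expect_equal(fit$variance_explained,
               100 * ev$values[1:4] / sum(ev$values), tolerance = 1e-8)
  expect_equal(crossprod(fit$loadings), diag(4), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_true(all(diff(fit$variance_explained) <= 1e-12))
  expect_error(mosaic_pca(mos, 31), "n_comp")
})

test_that("exact rank-2 data is fully captured by two components", {
  set.seed(4)
  M <- cbind(rnorm(300)) %*% rbind(rnorm(20)) +
    cbind(rnorm(300)) %*% rbind(rnorm(20))
  mos <- build_mosaic(list(a = snv_cube_from(array(M, c(300, 1, 20)),
                                             wl = seq_len(20) * 50 + 1000)))
  fit <- mosaic_pca(mos, 2)
  expect_equal(sum(fit$variance_explained), 100, tolerance = 1e-8)
})

test_that("isotropic noise spreads variance roughly evenly", {
  set.seed(5)
  M <- matrix(rnorm(3000 * 10), 3000, 10)
  mos <- build_mosaic(list(a = snv_cube_from(array(M, c(3000, 1, 10)),
                                             wl = 1:10 * 100 + 1000)))
  fit <- mosaic_pca(mos, 4)
  expect_true(all(abs(fit$variance_explained - 10) / 10 < 0.2))
})

test_that("PC1 extreme-pixel removal catches planted outliers once", {
  set.seed(6)
  n <- 5000; b <- 12
  M <- matrix(rnorm(n * b, sd = 0.3), n, b)
  dir1 <- rnorm(b); dir1 <- dir1 / sqrt(sum(dir1^2))
  M <- M + cbind(rnorm(n)) %*% rbind(dir1)          # dominant direction
  out_idx <- sample.int(n, 100)
  M[out_idx, ] <- M[out_idx, ] + 25 * matrix(dir1, 100, b, byrow = TRUE)
  mos <- build_mosaic(list(a = snv_cube_from(array(M, c(n, 1, b)),
                                             wl = seq_len(b) * 100 + 1000)))
  fit <- mosaic_pca(mos, 3)
  res <- remove_extreme_pixels(fit, mos)
  expect_gte(sum(res$excluded[out_idx]), 95)
  expect_lte(sum(res$excluded[-out_idx]), 0.02 * n)
  ## second application of the rule to the refitted model removes ~nothing
  res2 <- remove_extreme_pixels(res$model, res$mosaic)
  expect_lt(mean(res2$excluded), 0.01)
  ## clean data: nothing removed, refit agrees with the original up to sign
  M0 <- matrix(rnorm(800 * b, sd = 0.2), 800, b) + cbind(rnorm(800)) %*% rbind(dir1)
  mos0 <- build_mosaic(list(a = snv_cube_from(array(M0, c(800, 1, b)),
                                              wl = seq_len(b) * 100 + 1000)))
  fit0 <- mosaic_pca(mos0, 2)
  res0 <- remove_extreme_pixels(fit0, mos0, k_sd = 10)
  expect_equal(sum(res0$excluded), 0)
  expect_lt(max(abs(abs(res0$model$loadings) - abs(fit0$loadings))), 1e-8)
  ## over-aggressive threshold errors
  expect_error(remove_extreme_pixels(fit0, mos0, k_sd = 0.1), "review k_sd")
})

test_that("score refolding restores geometry with NA at excluded pixels", {
  cfg <- tiny_config(seed = 31)
  run <- phantom_imaging_run(cfg, positions = c(1, 4, 7))
  fit <- mosaic_pca(run$mosaic, 2)
  maps <- score_images(fit, run$mosaic)
  expect_named(maps, c("pos1", "pos4", "pos7"))
  im <- run$mosaic$index_map
  sel <- which(im$sample == "pos4")[1:50]
  for (i in sel)
    expect_equal(maps$pos4[im$row[i], im$col[i], 1], fit$scores[i, 1])
  ## background pixels (absent from the mosaic) are NA
  bg <- run$truth$pos4$tissue == "background"
  expect_true(all(is.na(maps$pos4[, , 1][bg])))
})

test_that("mean PC1 scores order the phantom positions monotonically", {
  cfg <- tiny_config(seed = 32)
  run <- phantom_imaging_run(cfg)
  fit0 <- mosaic_pca(run$mosaic, 4)
  res <- remove_extreme_pixels(fit0, run$mosaic)
  im <- res$mosaic$index_map
  mu <- tapply(res$model$scores[, 1], im$sample, mean)[paste0("pos", 1:7)]
  rho <- cor(1:7, as.vector(mu), method = "spearman")
  expect_gte(abs(rho), 0.9)   # sign is a PCA convention
})
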