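#' Spatial median filter
#'
#' Per-band 2-D median over a moving odd square window (default 3 x 3),
#' the standard despiking step for line-scan hyperspectral images.
#' Edges are handled by reflect padding.
#'
#' @param cube a raw-stage [hs_cube()].
#' @param window odd integer window side length.
#' @return The filtered cube, still at stage `raw`.
#' @export
median_filter_cube <- function(cube, window = 3L) {
  cube_check_stage(cube, "raw", "median_filter_cube")
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be an odd integer >= 1")
  d <- dim(cube$values)
  out <- .median_filter3d(as.numeric(cube$values), d[1], d[2], d[3], window)
  cube$values <- array(out, d)
  cube$meta$median_window <- window
  cube
}

#' Dark/white reflectance calibration
#'
#' Converts raw counts to unitless reflectance,
#' `r = (raw - dark) / (white - dark)`, broadcasting 1 x cols x bands
#' line-scan reference frames over image rows. Values are clipped from
#' below at `eps` (recorded in metadata); pixels where
#' `white - dark <= 0` at any band are flagged into an invalid mask
#' rather than silently clipped.
#'
#' @param raw_cube raw-stage [hs_cube()].
#' @param white_frame,dark_frame arrays of shape rows x cols x bands or
#'   1 x cols x bands (line-scan), count units.
#' @param eps lower clip bound for reflectance.
#' @return A reflectance-stage cube; `meta$invalid_mask` is a logical
#'   rows x cols matrix (TRUE = unusable pixel), `meta$saturation_mask`
#'   marks pixels whose raw counts reached detector full scale (when
#'   `meta$detector_full_scale` is set on the input cube).
#' @export
to_reflectance <- function(raw_cube, white_frame, dark_frame, eps = 1e-6) {
  cube_check_stage(raw_cube, "raw", "to_reflectance")
  d <- dim(raw_cube$values)
  expand <- function(fr) {
    fd <- dim(fr)
    if (length(fd) != 3L || fd[2] != d[2] || fd[3] != d[3])
      stop("reference frame must be rows|1 x cols x bands")
    if (fd[1] == d[1]) return(fr)
    if (fd[1] != 1L) stop("reference frame rows must be 1 or match the cube")
    out <- array(0, d)
    for (b in seq_len(d[3])) out[, , b] <- rep(fr[1, , b], each = d[1])
    out
  }
  wf <- expand(white_frame); df <- expand(dark_frame)
  denom <- wf - df
  invalid <- apply(denom <= 0, c(1, 2), any)
  denom[denom <= 0] <- NA_real_
  r <- (raw_cube$values - df) / denom
  r[r < eps] <- eps
  meta <- raw_cube$meta
  meta$reflectance_eps <- eps
  meta$invalid_mask <- invalid
  if (!is.null(meta$detector_full_scale))
    meta$saturation_mask <-
      apply(raw_cube$values >= meta$detector_full_scale, c(1, 2), any)
  hs_cube(r, raw_cube$wavelengths, stage = "reflectance", meta = meta)
}

#' Standard normal variate transformation
#'
#' Standardizes each spectrum to mean 0 and standard deviation 1
#' (n-1 denominator), removing per-pixel multiplicative scatter and
#' offset. Accepts a spectra matrix (rows = spectra) or an
#' [hs_cube()] at reflectance or absorbance stage. Zero-variance
#' spectra are flagged invalid (rows of `NA` plus an `invalid`
#' attribute / mask entry), never divided.
#'
#' @param x matrix (spectra x bands) or [hs_cube()].
#' @param tol variance tolerance below which a spectrum is degenerate.
#' @return Same shape as the input. For cubes the stage becomes
#'   `"snv"` and `meta$snv_input` records what was standardized;
#'   invalid pixels are merged into `meta$invalid_mask`.
#' @export
snv <- function(x, tol = 1e-12) {
  if (inherits(x, "hs_cube")) {
    cube_check_stage(x, c("reflectance", "absorbance"), "snv")
    d <- dim(x$values)
    m <- matrix(x$values, d[1] * d[2], d[3])
    sm <- snv(m, tol = tol)
    invalid <- matrix(attr(sm, "invalid"), d[1], d[2])
    meta <- x$meta
    meta$snv_input <- x$stage
    meta$invalid_mask <- if (is.null(meta$invalid_mask)) invalid
                         else meta$invalid_mask | invalid
    return(hs_cube(array(sm, d), x$wavelengths, stage = "snv", meta = meta))
  }
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("snv needs spectra with >= 2 bands")
  mu <- rowMeans(x)
  s <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
  invalid <- !is.finite(s) | s < tol
  s[invalid] <- NA_real_
  out <- (x - mu) / s
  attr(out, "invalid") <- invalid
  out
}

#' PCA background and saturation mask
#'
#' Identifies background and saturated pixels of an SNV-stage cube by
#' PCA over the unfolded pixel spectra: pixels whose score on the
#' dominant component lies more than `k_sd` robust standard deviations
#' (median absolute deviation scaled to the normal) from the median
#' score are masked out, as are pixels flagged saturated or invalid
#' during calibration/SNV.
#'
#' @param cube an SNV-stage [hs_cube()].
#' @param k_sd robust-SD multiple for the PC1 score thresholds.
#' @param retain_min minimum fraction of retained pixels below which
#'   the call errors (guards against misconfigured thresholds).
#' @return logical rows x cols matrix, `TRUE` = retained pixel.
#' @export
background_mask <- function(cube, k_sd = 4, retain_min = 0.10) {
  cube_check_stage(cube, "snv", "background_mask")
  d <- dim(cube$values)
  m <- matrix(cube$values, d[1] * d[2], d[3])
  invalid <- if (!is.null(cube$meta$invalid_mask))
    as.vector(cube$meta$invalid_mask) else rep(FALSE, nrow(m))
  ok <- !invalid & !apply(is.na(m), 1, any)
  mc <- scale(m[ok, , drop = FALSE], center = TRUE, scale = FALSE)
  p1 <- svd(mc, nu = 0L, nv = 1L)$v[, 1]
  s1 <- as.vector(mc %*% p1)
  med <- median(s1); rsd <- mad(s1)
  if (rsd == 0) rsd <- sd(s1)
  keep_ok <- abs(s1 - med) <= k_sd * rsd
  keep <- rep(FALSE, nrow(m))
  keep[ok] <- keep_ok
  if (!is.null(cube$meta$saturation_mask))
    keep[as.vector(cube$meta$saturation_mask)] <- FALSE
  if (mean(keep) < retain_min)
    stop(sprintf("background mask retains only %.1f%% of pixels; check thresholds",
                 100 * mean(keep)))
  matrix(keep, d[1], d[2])
}

#' Extract a region of interest
#'
#' Cuts a `height x width` sub-image, either centered (ties rounded
#' toward the top-left, i.e. floor division of the margins) or at an
#' explicit 0-based offset.
#'
#' @param cube an [hs_cube()] at any stage.
#' @param height,width ROI size in pixels (defaults 281 x 301).
#' @param row_offset,col_offset 0-based offsets for `anchor="explicit"`.
#' @param anchor `"center"` or `"explicit"`.
#' @return list with `cube` (the sub-cube) and `offsets`
#'   (0-based `c(row, col)` actually used).
#' @export
select_roi <- function(cube, height = 281L, width = 301L,
                       row_offset = NULL, col_offset = NULL,
                       anchor = c("center", "explicit")) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(cube, "hs_cube"))
  d <- dim(cube$values)
  if (height > d[1] || width > d[2])
    stop(sprintf("ROI %d x %d exceeds cube %d x %d; need a cube of at least %d x %d",
                 height, width, d[1], d[2], height, width))
  if (anchor == "center") {
    row_offset <- (d[1] - height) %/% 2L
    col_offset <- (d[2] - width) %/% 2L
  } else if (is.null(row_offset) || is.null(col_offset)) {
    stop("explicit anchor requires row_offset and col_offset")
  }
  if (row_offset < 0 || col_offset < 0 ||
      row_offset + height > d[1] || col_offset + width > d[2])
    stop("ROI out of bounds")
  rows <- row_offset + seq_len(height)
  cols <- col_offset + seq_len(width)
  sub <- cube
  sub$values <- cube$values[rows, cols, , drop = FALSE]
  for (nm in c("invalid_mask", "saturation_mask"))
    if (!is.null(sub$meta[[nm]]))
      sub$meta[[nm]] <- sub$meta[[nm]][rows, cols, drop = FALSE]
  list(cube = sub, offsets = c(row = row_offset, col = col_offset))
}

#' Reflectance to absorbance
#'
#' `A = log10(1 / r)` elementwise.
#'
#' @param reflectance_cube a reflectance-stage [hs_cube()].
#' @return An absorbance-stage cube.
#' @export
to_absorbance <- function(reflectance_cube) {
  cube_check_stage(reflectance_cube, "reflectance", "to_absorbance")
  if (any(reflectance_cube$values <= 0, na.rm = TRUE))
    stop("nonpositive reflectance encountered; calibrate with clipping first")
  out <- reflectance_cube
  out$values <- log10(1 / reflectance_cube$values)
  out$stage <- "absorbance"
  out
}

#' Trim the wavelength axis
#'
#' Retains bands with `low <= lambda <= high` (both ends inclusive);
#' works on an [hs_cube()] or on a spectra matrix with a `wavelengths`
#' argument/attribute.
#'
#' @param x [hs_cube()] or spectra matrix.
#' @param low,high band range in nm (defaults 1100-2400).
#' @param wavelengths required when `x` is a matrix.
#' @return Same kind as the input, with the wavelength vector subset
#'   (matrices carry it as attribute `wavelengths`).
#' @export
trim_bands <- function(x, low = 1100, high = 2400, wavelengths = NULL) {
  if (low >= high) stop("low must be < high")
  if (inherits(x, "hs_cube")) {
    keep <- x$wavelengths >= low & x$wavelengths <= high
    if (!any(keep)) stop("no bands retained in [", low, ", ", high, "] nm")
    x$values <- x$values[, , keep, drop = FALSE]
    x$wavelengths <- x$wavelengths[keep]
    return(x)
  }
  wl <- if (!is.null(wavelengths)) wavelengths else attr(x, "wavelengths")
  if (is.null(wl)) stop("matrix input needs `wavelengths`")
  keep <- wl >= low & wl <= high
  if (!any(keep)) stop("no bands retained in [", low, ", ", high, "] nm")
  out <- x[, keep, drop = FALSE]
  attr(out, "wavelengths") <- wl[keep]
  out
}

#' Masked average spectrum of a sample
#'
#' Arithmetic mean over retained pixels, per band.
#'
#' @param cube an [hs_cube()].
#' @param mask logical rows x cols matrix, `TRUE` = retained; `NULL`
#'   keeps all pixels.
#' @param sample_id identifier carried into the result.
#' @return list of class `sample_spectrum`: `values` (band vector),
#'   `wavelengths`, `n_pixels_averaged`, `sample_id`, `stage`.
#' @export
average_spectrum <- function(cube, mask = NULL, sample_id = "sample") {
  stopifnot(inherits(cube, "hs_cube"))
  d <- dim(cube$values)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!identical(dim(mask), d[1:2])) stop("mask shape must match the cube")
  if (!any(mask)) stop("empty mask: no pixels to average")
  m <- matrix(cube$values, d[1] * d[2], d[3])
  v <- colMeans(m[as.vector(mask), , drop = FALSE])
  structure(list(values = v, wavelengths = cube$wavelengths,
                 n_pixels_averaged = sum(mask), sample_id = sample_id,
                 stage = cube$stage),
            class = "sample_spectrum")
}

#' Preprocess a raw phantom/camera cube to an analysis-ready ROI
#'
#' Convenience chain implementing the standard sequencing: median
#' filter on raw counts, reflectance calibration, SNV of reflectance
#' for PCA background/saturation masking, then (independently) ROI
#' extraction, absorbance conversion, SNV and band trimming for
#' analysis. The SNV-absorbance path feeds ASCA averages and mosaic
#' PCA; `snv_on` switches to SNV-reflectance if preferred.
#'
#' @param raw_cube raw [hs_cube()].
#' @param white_frame,dark_frame calibration frames.
#' @param roi_height,roi_width ROI size (clamped to the image if the
#'   phantom is smaller than the camera default 281 x 301).
#' @param band_low,band_high trim range in nm.
#' @param window median filter window.
#' @param snv_on `"absorbance"` (default) or `"reflectance"`: which
#'   stage the analysis SNV standardizes.
#' @param mask_k_sd robust-SD multiple for [background_mask()].
#' @return list: `roi` (SNV-stage trimmed ROI cube), `mask` (retained
#'   pixels within the ROI), `average` ([average_spectrum()] of the
#'   ROI), `full_mask` (whole-image mask), `offsets`.
#' @export
preprocess_cube <- function(raw_cube, white_frame, dark_frame,
                            roi_height = 281L, roi_width = 301L,
                            band_low = 1100, band_high = 2400,
                            window = 3L, snv_on = c("absorbance", "reflectance"),
                            mask_k_sd = 4) {
  snv_on <- match.arg(snv_on)
  d <- dim(raw_cube$values)
  roi_height <- min(roi_height, d[1]); roi_width <- min(roi_width, d[2])
  filtered <- median_filter_cube(raw_cube, window)
  refl <- to_reflectance(filtered, white_frame, dark_frame)
  full_mask <- background_mask(snv(refl), k_sd = mask_k_sd)
  roi <- select_roi(refl, roi_height, roi_width)
  roi_mask <- full_mask[roi$offsets["row"] + seq_len(roi_height),
                        roi$offsets["col"] + seq_len(roi_width), drop = FALSE]
  analysis <- if (snv_on == "absorbance") snv(to_absorbance(roi$cube))
              else snv(roi$cube)
  if (!is.null(analysis$meta$invalid_mask))
    roi_mask <- roi_mask & !analysis$meta$invalid_mask
  analysis <- trim_bands(analysis, band_low, band_high)
  avg <- average_spectrum(analysis, roi_mask,
                          sample_id = raw_cube$meta$position %||% "sample")
  list(roi = analysis, mask = roi_mask, average = avg,
       full_mask = full_mask, offsets = roi$offsets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
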