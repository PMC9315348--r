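#' Phantom configuration
#'
#' Geometry, chemistry and acquisition parameters for synthetic
#' wood-decay images. The phantom emulates a radial wood surface:
#' vertical earlywood/latewood stripes of period `ring_period` pixels
#' (an annual-ring analogue), an optional border of near-zero
#' reflectance background, a position-dependent decay fraction that is
#' always at least as high in earlywood as in latewood, per-pixel
#' multiplicative scatter, additive detector noise and raw-count
#' encoding against dark and white reference frames.
#'
#' @param image_rows,image_cols image size in pixels.
#' @param n_bands number of spectral bands (default 288).
#' @param wavelength_range length-2 nm range (default 930-2550).
#' @param ring_period stripe period in pixels.
#' @param earlywood_fraction fraction of each period that is earlywood.
#' @param background_border width (pixels) of background frame; 0 = none.
#' @param decay_by_position data.frame with columns `position` (1-7),
#'   `earlywood`, `latewood`: decay fraction d in \[0,1\] per tissue.
#'   Defaults to a linear earlywood ramp 0.05-0.95 with latewood at 60%
#'   of earlywood, mimicking earlywood-first brown rot.
#' @param base_carb carbohydrate mass fraction of sound wood (0-1).
#' @param tissue_carb_offset optional carbohydrate-fraction deficit of
#'   undegraded earlywood relative to latewood; default 0.
#' @param scatter_gain_sd,scatter_offset_sd per-pixel multiplicative
#'   scatter gain/offset standard deviations (unitless).
#' @param noise_sd additive detector noise SD, count units.
#' @param detector_full_scale detector saturation level, counts.
#' @param dark_level,white_level nominal dark and white frame counts.
#' @param seed integer RNG seed.
#' @return A validated list of class `phantom_config`.
#' @export
phantom_config <- function(image_rows = 140, image_cols = 120,
                           n_bands = 288, wavelength_range = c(930, 2550),
                           ring_period = 24, earlywood_fraction = 0.6,
                           background_border = 8,
                           decay_by_position = NULL,
                           base_carb = 0.65, tissue_carb_offset = 0,
                           scatter_gain_sd = 0.05, scatter_offset_sd = 0.01,
                           noise_sd = 30, detector_full_scale = 65535,
                           dark_level = 1500, white_level = 52000,
                           seed = 1L) {
  if (is.null(decay_by_position)) {
    de <- seq(0.05, 0.95, length.out = 7)
    decay_by_position <- data.frame(position = 1:7, earlywood = de,
                                    latewood = 0.6 * de)
  }
  cfg <- list(image_rows = as.integer(image_rows),
              image_cols = as.integer(image_cols),
              n_bands = as.integer(n_bands),
              wavelength_range = as.numeric(wavelength_range),
              ring_period = as.integer(ring_period),
              earlywood_fraction = earlywood_fraction,
              background_border = as.integer(background_border),
              decay_by_position = decay_by_position,
              base_carb = base_carb,
              tissue_carb_offset = tissue_carb_offset,
              scatter_gain_sd = scatter_gain_sd,
              scatter_offset_sd = scatter_offset_sd,
              noise_sd = noise_sd,
              detector_full_scale = detector_full_scale,
              dark_level = dark_level, white_level = white_level,
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  d <- cfg$decay_by_position
  if (any(d$earlywood < 0 | d$earlywood > 1 | d$latewood < 0 | d$latewood > 1))
    stop("decay fractions must lie in [0, 1]")
  if (any(d$earlywood < d$latewood))
    stop("earlywood decay must be >= latewood decay at every position")
  if (cfg$earlywood_fraction <= 0 || cfg$earlywood_fraction >= 1)
    stop("earlywood_fraction must be in (0, 1)")
  if (cfg$base_carb <= 0 || cfg$base_carb > 1)
    stop("base_carb must be in (0, 1]")
  if (cfg$ring_period < 2) stop("ring_period must be >= 2 pixels")
  invisible(cfg)
}

phantom_wavelengths <- function(cfg)
  seq(cfg$wavelength_range[1], cfg$wavelength_range[2], length.out = cfg$n_bands)

## tissue layout: vertical stripes; background border all around
phantom_tissue_mask <- function(cfg) {
  m <- matrix("latewood", cfg$image_rows, cfg$image_cols)
  interior_col <- seq_len(cfg$image_cols) > cfg$background_border &
    seq_len(cfg$image_cols) <= cfg$image_cols - cfg$background_border
  phase <- ((seq_len(cfg$image_cols) - cfg$background_border - 1) %%
              cfg$ring_period) / cfg$ring_period
  early_col <- phase < cfg$earlywood_fraction
  m[, early_col] <- "earlywood"
  b <- cfg$background_border
  if (b > 0) {
    m[c(seq_len(b), cfg$image_rows - seq_len(b) + 1L), ] <- "background"
    m[, c(seq_len(b), cfg$image_cols - seq_len(b) + 1L)] <- "background"
  }
  m
}

## carbohydrate mass fraction at decay level d for a tissue
phantom_carb_fraction <- function(cfg, tissue, d) {
  b <- cfg$base_carb - ifelse(tissue == "earlywood", cfg$tissue_carb_offset, 0)
  b * (1 - d)
}

#' Generate one raw-count phantom cube with ground truth
#'
#' Builds an absorbance image as a per-pixel mixture of the library's
#' carbohydrate and lignin spectra, with the carbohydrate coefficient
#' decreasing in the decay fraction of the pixel's tissue (brown rot
#' consumes carbohydrates, enriching lignin), converts to reflectance
#' (`r = 10^-A`), applies per-pixel multiplicative scatter, and encodes
#' to raw counts against dark and white line-scan reference frames with
#' additive Gaussian noise. Background border pixels get a flat,
#' near-zero reflectance.
#'
#' @param config a [phantom_config()].
#' @param library a [component_library()].
#' @param position sample position 1-7 selecting the decay level.
#' @param seed RNG seed; defaults to `config$seed + position` so a
#'   series over positions uses distinct, reproducible streams.
#' @return list with `cube` (raw-count [hs_cube()]), `white_frame` and
#'   `dark_frame` (1 x cols x bands line-scan arrays), and `truth`
#'   (list: `tissue_mask`, `decay_map`, `mixing_map` rows x cols x 2
#'   with carbohydrate and lignin coefficients summing to 1,
#'   `absorbance` the noise-free absorbance cube).
#' @export
make_phantom_cube <- function(config, library = component_library(),
                              position,
                              seed = config$seed + as.integer(position)) {
  validate_phantom_config(config)
  position <- as.integer(position)
  dp <- config$decay_by_position
  if (!position %in% dp$position) stop("position must be one of decay_by_position$position")
  set.seed(seed)
  wl <- phantom_wavelengths(config)
  S <- make_component_spectra(wl, library)
  if (!all(c("carbohydrate", "lignin") %in% rownames(S)))
    stop("library must contain 'carbohydrate' and 'lignin' components")
  nr <- config$image_rows; nc <- config$image_cols; nb <- config$n_bands
  tissue <- phantom_tissue_mask(config)
  d_row <- dp[dp$position == position, ]
  decay_map <- matrix(0, nr, nc)
  decay_map[tissue == "earlywood"] <- d_row$earlywood
  decay_map[tissue == "latewood"] <- d_row$latewood
  c_carb <- matrix(NA_real_, nr, nc)
  for (tt in c("earlywood", "latewood")) {
    idx <- tissue == tt
    c_carb[idx] <- phantom_carb_fraction(config, tt, decay_map[idx])
  }
  ## absorbance cube: pixels x bands then fold
  A <- matrix(0, nr * nc, nb)
  wood <- tissue != "background"
  cc <- c_carb[wood]
  A[wood, ] <- cc %o% S["carbohydrate", ] + (1 - cc) %o% S["lignin", ]
  bg_r <- 0.02  # flat dark background
  A[!wood, ] <- -log10(bg_r)
  r <- 10^(-A)
  gain <- 1 + rnorm(nr * nc, 0, config$scatter_gain_sd)
  offs <- rnorm(nr * nc, 0, config$scatter_offset_sd)
  r_obs <- r * gain + offs
  bad <- r_obs <= 0 | r_obs > 1
  if (mean(bad) > 0.01)
    stop(sprintf(paste("%.1f%% of pixel reflectances fall outside (0, 1];",
                       "rescale component amplitudes or scatter parameters"),
                 100 * mean(bad)))
  r_obs[r_obs <= 0] <- 1e-6
  r_obs[r_obs > 1] <- 1
  ## line-scan reference frames: flat across the scan line, with a
  ## smooth halogen-lamp spectral profile across bands
  lamp <- 0.75 + 0.25 * sin(pi * (wl - wl[1]) / diff(range(wl)))
  dark_b <- rep(config$dark_level, nb)
  white_b <- config$white_level * lamp
  counts_mat <- sweep(r_obs, 2, white_b - dark_b, "*")
  counts_mat <- sweep(counts_mat, 2, dark_b, "+")
  if (config$noise_sd > 0)
    counts_mat <- counts_mat + rnorm(length(counts_mat), 0, config$noise_sd)
  counts_mat[counts_mat > config$detector_full_scale] <- config$detector_full_scale
  counts <- array(counts_mat, c(nr, nc, nb))
  dark <- array(rep(dark_b, each = nc), c(1, nc, nb))
  white <- array(rep(white_b, each = nc), c(1, nc, nb))
  cube <- hs_cube(counts, wl, stage = "raw",
                  meta = list(position = position, seed = seed,
                              detector_full_scale = config$detector_full_scale))
  mixing <- array(c(c_carb, 1 - c_carb), c(nr, nc, 2),
                  dimnames = list(NULL, NULL, c("carbohydrate", "lignin")))
  mixing[array(rep(tissue == "background", 2), c(nr, nc, 2))] <- NA_real_
  list(cube = cube, white_frame = white, dark_frame = dark,
       truth = list(tissue_mask = tissue, decay_map = decay_map,
                    mixing_map = mixing,
                    absorbance = hs_cube(array(A, c(nr, nc, nb)), wl,
                                         stage = "absorbance")))
}

#' Generate a phantom series over sample positions
#'
#' One cube per position, sharing config, library and reference-frame
#' model; the decay fraction rises with position so the series mimics a
#' stacked-sample decay test read from the inoculum upward.
#'
#' @inheritParams make_phantom_cube
#' @param positions positions to generate (default all in the config).
#' @return named list of [make_phantom_cube()] results ("pos1", ...).
#' @export
make_phantom_series <- function(config, library = component_library(),
                                positions = config$decay_by_position$position) {
  out <- lapply(positions, function(p) make_phantom_cube(config, library, p))
  names(out) <- paste0("pos", positions)
  out
}

#' Write a phantom dataset to disk
#'
#' Writes each cube as an ENVI raster + header, the reference frames as
#' ENVI rasters, and ground truth (tissue mask, decay map, mixing map)
#' plus the design as CSV files.
#'
#' @param series result of [make_phantom_series()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(series)) {
    ph <- series[[nm]]
    write_envi(ph$cube, file.path(dir, nm))
    write_envi(hs_cube(ph$white_frame, ph$cube$wavelengths, "raw"),
               file.path(dir, paste0(nm, "_white")))
    write_envi(hs_cube(ph$dark_frame, ph$cube$wavelengths, "raw"),
               file.path(dir, paste0(nm, "_dark")))
    write.csv(ph$truth$tissue_mask, file.path(dir, paste0(nm, "_tissue.csv")),
              row.names = FALSE)
    write.csv(ph$truth$decay_map, file.path(dir, paste0(nm, "_decay.csv")),
              row.names = FALSE)
  }
  invisible(dir)
}
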