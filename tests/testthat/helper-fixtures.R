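# Shared fixtures: small phantom configurations and independent oracles.

tiny_config <- function(seed = 1L, ...) {
  args <- modifyList(list(image_rows = 48L, image_cols = 48L, n_bands = 48L,
                          ring_period = 12L, background_border = 5L,
                          noise_sd = 15, scatter_gain_sd = 0.03,
                          scatter_offset_sd = 0.005, seed = seed),
                     list(...))
  do.call(phantom_config, args)
}

noise_free_config <- function(seed = 1L, ...) {
  tiny_config(seed = seed, noise_sd = 0, scatter_gain_sd = 0,
              scatter_offset_sd = 0, ...)
}

# Brute-force median filter with reflect padding (independent of the
# compiled kernel).
oracle_median_filter <- function(arr, window) {
  h <- window %/% 2
  reflect <- function(i, n) {
    period <- 2 * n
    i <- ((i %% period) + period) %% period
    ifelse(i < n, i, period - 1 - i)
  }
  d <- dim(arr)
  out <- array(NA_real_, d)
  for (b in seq_len(d[3])) for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    vals <- c()
    for (dr in -h:h) for (dc in -h:h) {
      rr <- reflect(r - 1 + dr, d[1]) + 1
      cc <- reflect(c - 1 + dc, d[2]) + 1
      vals <- c(vals, arr[rr, cc, b])
    }
    out[r, c, b] <- median(vals)
  }
  out
}

# Brute-force ASCA effect matrices by explicit cell-mean loops.
oracle_asca_effects <- function(X, design) {
  X <- sweep(X, 2, colMeans(X))
  n <- nrow(X)
  fnames <- names(design)
  main <- list()
  for (f in fnames) {
    M <- matrix(0, n, ncol(X))
    for (lv in unique(design[[f]])) {
      idx <- design[[f]] == lv
      M[idx, ] <- matrix(colMeans(X[idx, , drop = FALSE]), sum(idx),
                         ncol(X), byrow = TRUE)
    }
    main[[f]] <- M
  }
  out <- main
  if (length(fnames) > 1) {
    for (pr in utils::combn(fnames, 2, simplify = FALSE)) {
      M <- matrix(0, n, ncol(X))
      cells <- unique(design[pr])
      for (i in seq_len(nrow(cells))) {
        idx <- design[[pr[1]]] == cells[[pr[1]]][i] &
          design[[pr[2]]] == cells[[pr[2]]][i]
        M[idx, ] <- matrix(colMeans(X[idx, , drop = FALSE]), sum(idx),
                           ncol(X), byrow = TRUE)
      }
      out[[paste(pr, collapse = ":")]] <- M - main[[pr[1]]] - main[[pr[2]]]
    }
  }
  out
}

full_design <- function(n_pos = 7, n_fun = 2, n_rep = 5) {
  expand.grid(position = seq_len(n_pos), fungus = seq_len(n_fun),
              replicate = seq_len(n_rep), KEEP.OUT.ATTRS = FALSE)
}

# Run a phantom series through preprocessing to ROI cubes + masks +
# ROI-aligned ground truth (used by mosaic/cluster/acceptance tests).
phantom_imaging_run <- function(cfg, positions = cfg$decay_by_position$position) {
  series <- lapply(positions, function(p) make_phantom_cube(cfg, position = p))
  names(series) <- paste0("pos", positions)
  pre <- list(); truth <- list()
  for (nm in names(series)) {
    ph <- series[[nm]]
    cube <- ph$cube
    cube$meta$detector_full_scale <- cfg$detector_full_scale
    pp <- preprocess_cube(cube, ph$white_frame, ph$dark_frame)
    ro <- pp$offsets
    h <- dim(pp$roi$values)[1]; w <- dim(pp$roi$values)[2]
    truth[[nm]] <- list(
      tissue = ph$truth$tissue_mask[ro["row"] + seq_len(h),
                                    ro["col"] + seq_len(w), drop = FALSE],
      decay = ph$truth$decay_map[ro["row"] + seq_len(h),
                                 ro["col"] + seq_len(w), drop = FALSE])
    pre[[nm]] <- pp
  }
  mos <- build_mosaic(lapply(pre, `[[`, "roi"), masks = lapply(pre, `[[`, "mask"))
  list(series = series, pre = pre, truth = truth, mosaic = mos,
       positions = positions)
}

# tissue / decay truth aligned with mosaic pixel rows
mosaic_truth <- function(run) {
  im <- run$mosaic$index_map
  tissue <- character(nrow(im)); decay <- numeric(nrow(im))
  for (nm in names(run$truth)) {
    sel <- im$sample == nm
    tissue[sel] <- run$truth[[nm]]$tissue[cbind(im$row[sel], im$col[sel])]
    decay[sel] <- run$truth[[nm]]$decay[cbind(im$row[sel], im$col[sel])]
  }
  list(tissue = tissue, decay = decay)
}

nearest_band <- function(wavelengths, nm) which.min(abs(wavelengths - nm))

# three well-separated 4-D Gaussian blobs pointing in distinct directions
make_blobs <- function(n_per = 150, seed = 2) {
  set.seed(seed)
  centers <- rbind(c(6, 0, 0, 0), c(0, 6, 0, 0), c(0, 0, 6, 0))
  scores <- do.call(rbind, lapply(1:3, function(j)
    matrix(rnorm(n_per * 4, sd = 0.4), ncol = 4) +
      matrix(centers[j, ], n_per, 4, byrow = TRUE)))
  list(scores = scores, truth = rep(1:3, each = n_per))
}
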