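#' Assemble ROI cubes into an unfolded mosaic
#'
#' Unfolds the retained pixels of an ordered set of preprocessed ROI
#' cubes (one per sample, shared wavelength grid) into a pixels x bands
#' matrix, mean-centers it over all mosaic pixels, and keeps an index
#' map so scores and labels can be refolded back to image geometry.
#'
#' @param roi_cubes ordered list of [hs_cube()] ROIs (same stage and
#'   wavelength grid).
#' @param masks optional list of logical retain masks, one per cube;
#'   `NULL` retains everything.
#' @param sample_ids character ids; defaults to list names or "s1"...
#' @return An object of class `mosaic`: `spectra` (pixels x bands,
#'   centered), `center` (the subtracted mean spectrum), `index_map`
#'   (data.frame: sample, row, col), `layout` (per-sample dims),
#'   `wavelengths`.
#' @export
build_mosaic <- function(roi_cubes, masks = NULL, sample_ids = NULL) {
  stopifnot(length(roi_cubes) >= 1L)
  wl <- roi_cubes[[1]]$wavelengths
  for (cb in roi_cubes)
    if (!isTRUE(all.equal(cb$wavelengths, wl)))
      stop("all cubes must share the same wavelength grid")
  if (is.null(sample_ids))
    sample_ids <- names(roi_cubes) %||% paste0("s", seq_along(roi_cubes))
  blocks <- vector("list", length(roi_cubes))
  maps <- vector("list", length(roi_cubes))
  layout <- list()
  for (i in seq_along(roi_cubes)) {
    d <- dim(roi_cubes[[i]]$values)
    m <- matrix(roi_cubes[[i]]$values, d[1] * d[2], d[3])
    keep <- if (is.null(masks)) rep(TRUE, d[1] * d[2]) else as.vector(masks[[i]])
    keep <- keep & !apply(is.na(m), 1, any)
    ## row-major pixel order within each sample
    rows <- as.vector(row(matrix(0, d[1], d[2])))
    cols <- as.vector(col(matrix(0, d[1], d[2])))
    ord <- order(rows, cols)
    ord <- ord[keep[ord]]
    blocks[[i]] <- m[ord, , drop = FALSE]
    maps[[i]] <- data.frame(sample = sample_ids[i], row = rows[ord],
                            col = cols[ord], stringsAsFactors = FALSE)
    layout[[sample_ids[i]]] <- d[1:2]
  }
  spectra <- do.call(rbind, blocks)
  ctr <- colMeans(spectra)
  spectra <- sweep(spectra, 2, ctr)
  structure(list(spectra = spectra, center = ctr,
                 index_map = do.call(rbind, maps), layout = layout,
                 wavelengths = wl),
            class = "mosaic")
}

#' @export
print.mosaic <- function(x, ...) {
  cat(sprintf("<mosaic> %d pixels x %d bands from %d samples\n",
              nrow(x$spectra), ncol(x$spectra), length(x$layout)))
  invisible(x)
}

#' PCA of an unfolded mosaic
#'
#' Singular value decomposition of the centered pixels x bands matrix:
#' orthonormal spectral loadings, pixel scores `T = M P`, and the
#' percentage of variation captured per component. Component signs are
#' fixed so each loading's largest-magnitude element is positive.
#'
#' @param mosaic a [build_mosaic()] result.
#' @param n_comp number of components (default 4).
#' @return class `mosaic_pca`: `scores`, `loadings`, `singular_values`
#'   (all of them), `variance_explained` (% per retained component),
#'   `n_comp`, `excluded` (logical per pixel; all `FALSE` until
#'   [remove_extreme_pixels()]).
#' @export
mosaic_pca <- function(mosaic, n_comp = 4L) {
  stopifnot(inherits(mosaic, "mosaic"))
  M <- mosaic$spectra
  if (n_comp > min(dim(M))) stop("n_comp exceeds min(pixels, bands)")
  if (nrow(M) <= n_comp) stop("need more pixels than components")
  sv <- svd(M, nu = 0L, nv = n_comp)
  P <- sv$v
  for (j in seq_len(n_comp)) {
    i <- which.max(abs(P[, j]))
    if (P[i, j] < 0) P[, j] <- -P[, j]
  }
  Tm <- M %*% P
  structure(list(scores = Tm, loadings = P, singular_values = sv$d,
                 variance_explained = 100 * sv$d[seq_len(n_comp)]^2 / sum(sv$d^2),
                 n_comp = n_comp,
                 excluded = rep(FALSE, nrow(M))),
            class = "mosaic_pca")
}

#' @export
print.mosaic_pca <- function(x, ...) {
  cat("<mosaic_pca>", nrow(x$scores), "pixels,", x$n_comp, "components;",
      "variance (%):", paste(sprintf("%.1f", x$variance_explained),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Remove extreme pixels on PC1 and refit
#'
#' Pixels whose first-component score lies more than `k_sd` robust
#' standard deviations (scaled MAD) from the median PC1 score are
#' excluded, and the PCA is redetermined once on the remaining pixels
#' (re-centered). The exclusion mask indexes the original mosaic.
#'
#' @param model a [mosaic_pca()] fit.
#' @param mosaic the mosaic the model was fitted on.
#' @param k_sd robust-SD multiple (default 4).
#' @param max_excluded error if more than this fraction would be
#'   dropped (default 0.2).
#' @return list: `excluded` (logical per original pixel), `model`
#'   (refitted `mosaic_pca` carrying the mask), `mosaic` (the reduced
#'   mosaic).
#' @export
remove_extreme_pixels <- function(model, mosaic, k_sd = 4, max_excluded = 0.2) {
  stopifnot(inherits(model, "mosaic_pca"), inherits(mosaic, "mosaic"))
  s1 <- model$scores[, 1]
  med <- median(s1); rsd <- mad(s1)
  if (rsd == 0) rsd <- sd(s1)
  excl <- abs(s1 - med) > k_sd * rsd
  if (mean(excl) > max_excluded)
    stop(sprintf("PC1 threshold would exclude %.1f%% of pixels; review k_sd",
                 100 * mean(excl)))
  reduced <- mosaic
  reduced$spectra <- sweep(mosaic$spectra[!excl, , drop = FALSE], 2,
                           colMeans(mosaic$spectra[!excl, , drop = FALSE]))
  reduced$center <- mosaic$center +
    colMeans(mosaic$spectra[!excl, , drop = FALSE])
  reduced$index_map <- mosaic$index_map[!excl, , drop = FALSE]
  refit <- mosaic_pca(reduced, model$n_comp)
  refit$excluded <- excl
  list(excluded = excl, model = refit, mosaic = reduced)
}

#' Refold scores into per-sample images
#'
#' Places each retained pixel's component scores back at its (row, col)
#' position; excluded or masked pixels carry `NA`.
#'
#' @param model a `mosaic_pca` fit on `mosaic`.
#' @param mosaic the matching mosaic (its index map must align with the
#'   model's score rows).
#' @return named list, one `rows x cols x n_comp` array per sample.
#' @export
score_images <- function(model, mosaic) {
  stopifnot(inherits(model, "mosaic_pca"), inherits(mosaic, "mosaic"))
  if (nrow(model$scores) != nrow(mosaic$index_map))
    stop("index map does not match the fitted scores")
  refold_values(model$scores, mosaic, model$n_comp)
}

refold_values <- function(values, mosaic, depth) {
  values <- as.matrix(values)
  out <- lapply(mosaic$layout, function(d) array(NA_real_, c(d, depth)))
  im <- mosaic$index_map
  for (s in names(mosaic$layout)) {
    sel <- im$sample == s
    d <- mosaic$layout[[s]]
    for (k in seq_len(depth)) {
      plane <- matrix(NA_real_, d[1], d[2])
      plane[cbind(im$row[sel], im$col[sel])] <- values[sel, k]
      out[[s]][, , k] <- plane
    }
  }
  out
}
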