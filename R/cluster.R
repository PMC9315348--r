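#' Farthest-point centroid initialization
#'
#' Deterministic k-means seeding in score space: the first centroid is
#' the point with the largest Euclidean distance from the center of the
#' score cloud; each further centroid is the point maximizing the
#' minimum Euclidean distance to the centroids already chosen. Ties go
#' to the lowest pixel index.
#'
#' @param scores pixels x n_comp score matrix.
#' @param k number of centroids (>= 1, <= pixels).
#' @return k x n_comp matrix of initial centroids (actual data points).
#' @export
init_centroids <- function(scores, k) {
  scores <- as.matrix(scores)
  if (k < 1) stop("k must be >= 1")
  if (nrow(scores) < k) stop("need at least k points")
  ctr <- colMeans(scores)
  d2 <- rowSums(sweep(scores, 2, ctr)^2)
  chosen <- which.max(d2)          # ties: first (lowest) index
  if (k > 1) {
    dmin <- rowSums(sweep(scores, 2, scores[chosen, ])^2)
    for (i in seq_len(k - 1L)) {
      nxt <- which.max(dmin)
      chosen <- c(chosen, nxt)
      if (i < k - 1L)
        dmin <- pmin(dmin, rowSums(sweep(scores, 2, scores[nxt, ])^2))
    }
  }
  scores[chosen, , drop = FALSE]
}

row_standardize <- function(m) {
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2))
  s[s == 0] <- NA_real_
  (m - mu) / s
}

#' K-means clustering of PCA scores into decay classes
#'
#' Lloyd-style iteration on pixel score vectors: each pixel is assigned
#' to the centroid with which its score vector has the highest Pearson
#' correlation (`metric = "correlation"`, the default) or the smallest
#' Euclidean distance (`metric = "euclidean"`), and centroids are then
#' recomputed as arithmetic means of their members. Initial centroids
#' come from [init_centroids()] unless supplied. An emptied cluster is
#' reseeded with the point worst fit by its current centroid. Classes
#' are canonicalized by descending size (ties by ascending first-score
#' centroid) for reporting.
#'
#' @param scores pixels x n_comp matrix (n_comp >= 2 for the
#'   correlation metric).
#' @param k number of classes (default 3).
#' @param init optional k x n_comp initial centroid matrix.
#' @param metric `"correlation"` or `"euclidean"`.
#' @param max_iter,tol iteration cap and centroid-shift tolerance.
#' @return class `decay_class_map`: `labels` (per pixel, 1..k),
#'   `centroids`, `sizes`, `metric`, `converged`, `iterations`.
#' @export
kmeans_scores <- function(scores, k = 3L, init = NULL,
                          metric = c("correlation", "euclidean"),
                          max_iter = 300L, tol = 1e-6) {
  metric <- match.arg(metric)
  scores <- as.matrix(scores)
  n <- nrow(scores); p <- ncol(scores)
  if (metric == "correlation" && p < 2L)
    stop("correlation metric needs at least 2 score dimensions")
  if (n < k) stop("need at least k points")
  centroids <- if (is.null(init)) init_centroids(scores, k) else as.matrix(init)
  stopifnot(nrow(centroids) == k, ncol(centroids) == p)
  zs <- if (metric == "correlation") row_standardize(scores) else NULL
  labels <- rep(0L, n)
  fit <- rep(NA_real_, n)   # assignment quality per pixel
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    if (metric == "correlation") {
      zc <- row_standardize(centroids)
      sim <- zs %*% t(zc)               # proportional to Pearson r
      sim[is.na(sim)] <- -Inf
      new_labels <- max.col(sim, ties.method = "first")
      fit <- sim[cbind(seq_len(n), new_labels)]
    } else {
      d2 <- outer(rowSums(scores^2), rep(1, k)) -
        2 * scores %*% t(centroids) +
        outer(rep(1, n), rowSums(centroids^2))
      new_labels <- max.col(-d2, ties.method = "first")
      fit <- -d2[cbind(seq_len(n), new_labels)]
    }
    ## reseed empty clusters with the worst-fit point
    for (j in seq_len(k)) {
      if (!any(new_labels == j)) {
        worst <- which.min(fit)
        new_labels[worst] <- j
        fit[worst] <- Inf
      }
    }
    new_centroids <- rowsum(scores, new_labels, reorder = TRUE) /
      as.vector(table(factor(new_labels, levels = seq_len(k))))
    shift <- max(abs(new_centroids - centroids))
    stable <- identical(new_labels, labels)
    centroids <- new_centroids
    labels <- new_labels
    if (stable || shift < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("k-means did not converge in ", max_iter, " iterations")
  ## canonical class order: descending size, ties by ascending centroid[,1]
  sizes <- as.vector(table(factor(labels, levels = seq_len(k))))
  ord <- order(-sizes, centroids[, 1])
  relabel <- match(seq_len(k), ord)
  labels <- relabel[labels]
  centroids <- centroids[ord, , drop = FALSE]
  sizes <- sizes[ord]
  structure(list(labels = labels, centroids = centroids, sizes = sizes,
                 metric = metric, converged = converged, iterations = iter),
            class = "decay_class_map")
}

#' @export
print.decay_class_map <- function(x, ...) {
  cat("<decay_class_map>", length(x$sizes), "classes (", x$metric,
      "metric ), sizes:", paste(x$sizes, collapse = ", "),
      if (x$converged) "- converged\n" else "- NOT converged\n")
  invisible(x)
}

#' Mean-centered class spectra
#'
#' Per class, the mean spectrum of its member pixels in the centered
#' mosaic (already mean-centered against the global mosaic mean, so a
#' class that matches the overall average is a flat zero line).
#'
#' @param labels integer class labels aligned with the mosaic pixels.
#' @param mosaic the [build_mosaic()] result the labels refer to.
#' @param k number of classes (default `max(labels)`).
#' @return k x bands matrix; empty classes give `NA` rows with a
#'   warning.
#' @export
class_mean_spectra <- function(labels, mosaic, k = max(labels)) {
  stopifnot(inherits(mosaic, "mosaic"))
  if (length(labels) != nrow(mosaic$spectra))
    stop("labels must align with mosaic pixels")
  out <- matrix(NA_real_, k, ncol(mosaic$spectra))
  for (j in seq_len(k)) {
    sel <- labels == j
    if (!any(sel)) {
      warning("class ", j, " is empty")
      next
    }
    out[j, ] <- colMeans(mosaic$spectra[sel, , drop = FALSE])
  }
  rownames(out) <- paste0("class", seq_len(k))
  out
}

#' Refold class labels into per-sample images
#'
#' @param class_map a [kmeans_scores()] result.
#' @param mosaic the matching mosaic.
#' @return named list of integer label matrices (`NA` = excluded or
#'   background pixel).
#' @export
label_map <- function(class_map, mosaic) {
  stopifnot(inherits(class_map, "decay_class_map"), inherits(mosaic, "mosaic"))
  if (length(class_map$labels) != nrow(mosaic$index_map))
    stop("labels do not match the mosaic index map")
  maps <- refold_values(matrix(class_map$labels, ncol = 1), mosaic, 1L)
  lapply(maps, function(a) {
    m <- a[, , 1]
    mode(m) <- "integer"
    m
  })
}

#' Adjusted Rand index against a reference partition
#'
#' Chance-corrected agreement between two labelings, used to score
#' cluster recovery against phantom ground truth. Delegates to
#' `mclust::adjustedRandIndex` when available, else returns `NA`.
#'
#' @param labels,reference two partitions of the same pixels.
#' @return scalar ARI, or `NA` when mclust is not installed.
#' @export
cluster_ari <- function(labels, reference) {
  if (!requireNamespace("mclust", quietly = TRUE)) return(NA_real_)
  mclust::adjustedRandIndex(labels, reference)
}
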