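## ANOVA-simultaneous component analysis for balanced full factorials.
##
## The data matrix (samples x bands) is decomposed into main-effect and
## two-factor-interaction matrices by cell-mean contrasts; on a balanced
## design the effect matrices are mutually orthogonal, so their sums of
## squares partition the total variation exactly. Each effect matrix is
## then analyzed by SVD, residuals are projected onto the effect
## loadings to display within-level variation, and effect significance
## is assessed by permutation of the relevant factor labels.

check_balanced <- function(design) {
  tab <- table(design)
  length(unique(as.vector(tab))) == 1L && all(tab >= 1L)
}

factor_indices <- function(design) {
  lapply(design, function(col) as.integer(factor(col)))
}

## level-mean expansion for one grouping vector: rows = group mean of X
group_mean_rows <- function(X, g) {
  sums <- rowsum(X, g, reorder = TRUE)
  cnt <- as.vector(table(g))
  (sums / cnt)[g, , drop = FALSE]
}

#' Decompose a spectra matrix into factorial effect matrices
#'
#' Fits the ASCA decomposition `X = X_1 + ... + X_k + interactions + E`
#' for all main effects and two-factor interactions of the design:
#' main-effect rows are level means minus the grand mean, interaction
#' rows are cell means minus both marginal level means plus the grand
#' mean, and `E` is what remains. Sums of squares are reported per
#' effect as fractions of the total; on a balanced design they add up
#' to 100%.
#'
#' @param X numeric matrix, samples x bands, column-mean-centered
#'   (re-centered with a warning if not).
#' @param design data.frame of factors, one row per sample of `X`.
#'   Must be a balanced full factorial; unbalanced designs error.
#' @return An object of class `asca`: list with `effects` (each a list
#'   `name`, `values`, `ssq`, `ssq_fraction`), `residual`, `total_ssq`,
#'   `design`, and empty `p_values`.
#' @export
asca_decompose <- function(X, design) {
  X <- as.matrix(X)
  design <- as.data.frame(design)
  design <- design[vapply(design, function(c) length(unique(c)) > 1L, TRUE)]
  if (!ncol(design)) stop("design has no factors with > 1 level")
  if (nrow(design) != nrow(X)) stop("design rows must match spectra rows")
  if (!check_balanced(design))
    stop("ASCA requires a balanced full factorial design")
  cm <- colMeans(X)
  if (max(abs(cm)) > 1e-8) {
    warning("X was not column-mean-centered; centering now")
    X <- sweep(X, 2, cm)
  }
  idx <- factor_indices(design)
  fnames <- names(design)
  effects <- list()
  main <- list()
  for (f in fnames) {
    m <- group_mean_rows(X, idx[[f]])
    main[[f]] <- m
    effects[[f]] <- m
  }
  if (length(fnames) > 1L) {
    pairs <- utils::combn(fnames, 2, simplify = FALSE)
    for (pr in pairs) {
      g <- interaction(design[[pr[1]]], design[[pr[2]]], drop = TRUE)
      cell <- group_mean_rows(X, as.integer(g))
      effects[[paste(pr, collapse = ":")]] <-
        cell - main[[pr[1]]] - main[[pr[2]]]
    }
  }
  E <- X - Reduce(`+`, effects)
  total <- sum(X^2)
  frac <- function(s) if (total > 0) 100 * s / total else 0
  eff <- lapply(names(effects), function(nm) {
    v <- effects[[nm]]
    list(name = nm, values = v, ssq = sum(v^2), ssq_fraction = frac(sum(v^2)))
  })
  names(eff) <- names(effects)
  structure(list(effects = eff, residual = E,
                 residual_ssq = sum(E^2), total_ssq = total,
                 design = design, X = X, p_values = numeric(0),
                 n_permutations = NA_integer_),
            class = "asca")
}

#' @export
print.asca <- function(x, ...) {
  cat("<asca> balanced factorial decomposition,",
      nrow(x$X), "samples x", ncol(x$X), "bands\n")
  print(variation_table(x), row.names = FALSE)
  invisible(x)
}

#' Combine effect matrices into one sub-model
#'
#' Replaces the listed effects by their elementwise sum (e.g. position
#' and position x fungus, so all position-linked variation sits in one
#' sub-model). On a balanced design the parts are orthogonal, so the
#' combined SSQ equals the sum of the parts.
#'
#' @param model an `asca` object.
#' @param names character vector (>= 2 distinct) of effect names.
#' @return The model with a combined effect named `"a+b"` in place of
#'   the parts.
#' @export
combine_effects <- function(model, names) {
  stopifnot(inherits(model, "asca"))
  if (anyDuplicated(names)) stop("cannot combine an effect with itself")
  if (length(names) < 2L) stop("need at least two effects to combine")
  miss <- setdiff(names, names(model$effects))
  if (length(miss)) stop("unknown effects: ", paste(miss, collapse = ", "))
  vals <- lapply(model$effects[names], `[[`, "values")
  comb <- Reduce(`+`, vals)
  nm <- paste(names, collapse = "+")
  keep <- setdiff(names(model$effects), names)
  first <- match(names[1], names(model$effects))
  new_eff <- list(name = nm, values = comb, ssq = sum(comb^2),
                  ssq_fraction = 100 * sum(comb^2) / model$total_ssq)
  effects <- model$effects[keep]
  effects[[nm]] <- new_eff
  ## restore a sensible order: combined effect where its first part was
  ord <- append(keep, nm, after = min(first, length(keep) + 1L) - 1L)
  model$effects <- effects[ord]
  if (length(model$p_values)) {
    model$p_values <- model$p_values[setdiff(names(model$p_values), names)]
  }
  model
}

## SSQ of a main effect under a grouping (balanced): sum over levels of
## n_l * ||level mean||^2, for column-centered X
main_effect_ssq <- function(X, g) {
  sums <- rowsum(X, g, reorder = FALSE)
  cnt <- as.vector(rowsum(rep(1, length(g)), g, reorder = FALSE))
  sum(sums^2 / cnt)
}

interaction_ssq <- function(Z, cell, a, b) {
  ## Z already has both main effects removed; cell/a/b are integer labels
  main_effect_ssq(Z, cell) - main_effect_ssq(Z, a) - main_effect_ssq(Z, b)
}

#' Permutation test for an ASCA effect
#'
#' Tests one effect of the factorial by permutation: the statistic is
#' the effect sum of squares recomputed under random reassignment of
#' the sample labels. Under the default `"free"` scheme the rows of the
#' data are freely permuted against the design and the tested effect's
#' SSQ is recomputed from the factorial decomposition each time; under
#' a pure-noise null this test is exact for mains and interactions
#' alike (for interactions it is conservative when large main effects
#' are present). The `"residual"` scheme instead removes the other
#' estimated effects before permuting, trading exactness for power.
#' The p-value uses the add-one estimator
#' `(#{SSQ_perm >= SSQ_obs} + 1) / (n_perm + 1)`.
#'
#' @param X samples x bands matrix (centered as for [asca_decompose()]).
#' @param design balanced factorial design data.frame.
#' @param effect effect name: a factor name or `"a:b"`.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for reproducibility.
#' @param scheme label-permutation scheme for main effects: `"free"`
#'   (default) permutes the tested factor's labels on the observed
#'   data; `"residual"` first removes every other estimated effect so
#'   that only the tested effect plus residual variation enters the
#'   null. Interactions always use the residual-style scheme (both
#'   main effects removed before permuting cell labels).
#' @return The permutation p-value (scalar).
#' @export
permutation_test <- function(X, design, effect, n_perm = 10000, seed = NULL,
                             scheme = c("free", "residual")) {
  scheme <- match.arg(scheme)
  if (n_perm < 1) stop("n_perm must be >= 1")
  X <- as.matrix(X)
  design <- as.data.frame(design)
  X <- sweep(X, 2, colMeans(X))
  if (!is.null(seed)) set.seed(seed)
  parts <- strsplit(effect, ":", fixed = TRUE)[[1]]
  if (!all(parts %in% names(design)))
    stop("effect '", effect, "' not found in the design")
  n <- nrow(X)
  if (length(parts) == 1L) {
    g <- as.integer(factor(design[[parts]]))
    if (scheme == "residual") {
      model <- asca_decompose(X, design)
      others <- setdiff(names(model$effects), effect)
      for (nm in others) X <- X - model$effects[[nm]]$values
    }
    obs <- main_effect_ssq(X, g)
    exceed <- 0L
    for (i in seq_len(n_perm))
      if (main_effect_ssq(X, g[sample.int(n)]) >= obs) exceed <- exceed + 1L
  } else if (length(parts) == 2L) {
    a <- as.integer(factor(design[[parts[1]]]))
    b <- as.integer(factor(design[[parts[2]]]))
    cell <- as.integer(interaction(a, b, drop = TRUE))
    Z <- if (scheme == "residual")
      X - group_mean_rows(X, a) - group_mean_rows(X, b) else X
    obs <- interaction_ssq(Z, cell, a, b)
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      pm <- sample.int(n)
      if (interaction_ssq(Z, cell[pm], a[pm], b[pm]) >= obs)
        exceed <- exceed + 1L
    }
  } else stop("only main effects and two-factor interactions are supported")
  (exceed + 1) / (n_perm + 1)
}

#' SVD of an effect matrix
#'
#' Truncated singular value decomposition of one effect matrix into
#' orthonormal spectral loadings and sample scores. The sign of each
#' component is fixed so that the largest-magnitude loading element is
#' positive.
#'
#' @param effect an effect entry of an `asca` model (list with `name`
#'   and `values`) or a bare matrix.
#' @param n_comp number of components to retain (default 1); must not
#'   exceed the numerical rank of the matrix.
#' @return list of class `asca_component`: `effect_name`, `loadings`
#'   (bands x n_comp), `scores` (samples x n_comp), `singular_values`,
#'   `n_comp`.
#' @export
effect_svd <- function(effect, n_comp = 1L) {
  vals <- if (is.list(effect)) effect$values else effect
  nm <- if (is.list(effect)) effect$name else "effect"
  sv <- svd(vals)
  rank <- sum(sv$d > max(dim(vals)) * .Machine$double.eps * max(sv$d, 1e-300))
  if (n_comp > rank)
    stop(sprintf("n_comp = %d exceeds the rank bound %d of effect '%s'",
                 n_comp, rank, nm))
  P <- sv$v[, seq_len(n_comp), drop = FALSE]
  for (j in seq_len(n_comp)) {
    i <- which.max(abs(P[, j]))
    if (P[i, j] < 0) P[, j] <- -P[, j]
  }
  Tm <- vals %*% P
  structure(list(effect_name = nm, loadings = P, scores = Tm,
                 singular_values = sv$d[seq_len(n_comp)], n_comp = n_comp),
            class = "asca_component")
}

#' Project model residuals onto effect loadings
#'
#' Adds the projected scores `S = T + E P` to a component, displaying
#' the natural within-level variation around the effect scores.
#'
#' @param component an `asca_component` from [effect_svd()].
#' @param E residual matrix (samples x bands) of the fitted model.
#' @return The component with an added `projected_scores` element.
#' @export
project_residuals <- function(component, E) {
  stopifnot(inherits(component, "asca_component"))
  E <- as.matrix(E)
  if (ncol(E) != nrow(component$loadings))
    stop("residual band count does not match the loadings")
  component$projected_scores <- component$scores + E %*% component$loadings
  component
}

#' Variation table of an ASCA model
#'
#' One row per effect plus the residual: SSQ fraction (percent of the
#' total variation) and the permutation p-value when available. The
#' fractions, residual included, sum to 100 on balanced designs.
#'
#' @param model an `asca` object.
#' @return data.frame with columns `effect`, `variation_pct`,
#'   `p_value`.
#' @export
variation_table <- function(model) {
  stopifnot(inherits(model, "asca"))
  eff <- model$effects
  out <- data.frame(
    effect = c(vapply(eff, `[[`, "", "name"), "residual"),
    variation_pct = c(vapply(eff, `[[`, 0, "ssq_fraction"),
                      if (model$total_ssq > 0)
                        100 * model$residual_ssq / model$total_ssq else 0),
    p_value = NA_real_,
    stringsAsFactors = FALSE, row.names = NULL)
  if (length(model$p_values)) {
    i <- match(names(model$p_values), out$effect)
    out$p_value[i[!is.na(i)]] <- model$p_values[!is.na(i)]
  }
  out
}

#' Fit a full ASCA model with permutation tests and per-effect SVD
#'
#' Convenience wrapper: [asca_decompose()], then [permutation_test()]
#' for every effect, then [effect_svd()] (+ residual projection) for
#' every effect.
#'
#' @param X samples x bands matrix (SNV-scale average spectra).
#' @param design balanced factorial design data.frame (factor columns
#'   only).
#' @param n_perm permutations per effect; 0 skips testing.
#' @param n_comp components per effect SVD.
#' @param seed integer seed; effect-specific streams are derived from
#'   it.
#' @return An `asca` object with `p_values`, `n_permutations` and
#'   `components` filled in.
#' @export
asca <- function(X, design, n_perm = 10000, n_comp = 1L, seed = 1L) {
  model <- asca_decompose(X, design)
  if (n_perm > 0) {
    pv <- numeric(0)
    nms <- names(model$effects)
    for (i in seq_along(nms))
      pv[nms[i]] <- permutation_test(model$X, model$design, nms[i],
                                     n_perm = n_perm,
                                     seed = seed + i)
    model$p_values <- pv
    model$n_permutations <- as.integer(n_perm)
  }
  model$components <- lapply(model$effects, function(e) {
    rank <- qr(e$values)$rank
    if (rank == 0L) return(NULL)  # zero effect matrix: nothing to decompose
    comp <- effect_svd(e, n_comp = min(n_comp, rank))
    project_residuals(comp, model$residual)
  })
  model
}
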