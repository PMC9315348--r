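test_that("a one-factor two-level decomposition reproduces hand-computed effects", {
  X <- matrix(c(2, 4), 2, 1)
  Xc <- sweep(X, 2, colMeans(X))   # grand mean 3
  m <- asca_decompose(Xc, data.frame(a = c("lo", "hi")))
  expect_equal(m$effects$a$values, matrix(c(-1, 1), 2, 1),
               ignore_attr = TRUE)
  expect_equal(m$residual, matrix(0, 2, 1), ignore_attr = TRUE)
  expect_equal(m$effects$a$ssq_fraction, 100)
})

test_that("an all-zero matrix gives zero effects and zero fractions", {
  m <- asca_decompose(matrix(0, 12, 3), full_design(3, 2, 2))
  vt <- variation_table(m)
  expect_true(all(vt$variation_pct == 0))
  expect_true(all(vapply(m$effects, `[[`, 0, "ssq") == 0))
})

test_that("effect matrices match the brute-force cell-means oracle", {
  set.seed(7)
  for (rep in 1:3) {
    design <- full_design(3, 2, 2)
    X <- matrix(rnorm(nrow(design) * 4), ncol = 4)
    Xc <- sweep(X, 2, colMeans(X))
    m <- asca_decompose(Xc, design)
    oracle <- oracle_asca_effects(X, design)
    for (nm in names(oracle))
      expect_lt(max(abs(m$effects[[nm]]$values - oracle[[nm]])), 1e-12)
    ## SSQ additivity and reconstruction
    tot <- sum(vapply(m$effects, `[[`, 0, "ssq")) + m$residual_ssq
    expect_equal(tot, m$total_ssq, tolerance = 1e-10)
    recon <- Reduce(`+`, lapply(m$effects, `[[`, "values")) + m$residual
    expect_lt(max(abs(recon - Xc)), 1e-8)
    ## pairwise orthogonality
    mats <- c(lapply(m$effects, `[[`, "values"), list(m$residual))
    for (i in seq_along(mats)) for (j in seq_along(mats)) if (i < j)
      expect_lt(abs(sum(mats[[i]] * mats[[j]])), 1e-8 * m$total_ssq)
  }
})

test_that("unbalanced designs and uncentered input are handled explicitly", {
  design <- full_design(2, 2, 2)[-1, ]
  expect_error(asca_decompose(matrix(rnorm(7 * 3), 7), design), "balanced")
  X <- matrix(rnorm(8 * 3) + 5, 8)
  expect_warning(m <- asca_decompose(X, full_design(2, 2, 2)), "centered")
  expect_lt(max(abs(colMeans(m$X))), 1e-12)
})

test_that("combining effects sums matrices and fractions on balanced designs", {
  set.seed(8)
  design <- full_design(4, 2, 3)
  X <- matrix(rnorm(24 * 6), 24)
  m <- asca_decompose(sweep(X, 2, colMeans(X)), design)
  comb <- combine_effects(m, c("position", "position:fungus"))
  nm <- "position+position:fungus"
  expect_equal(comb$effects[[nm]]$values,
               m$effects$position$values + m$effects$`position:fungus`$values)
  expect_equal(comb$effects[[nm]]$ssq,
               m$effects$position$ssq + m$effects$`position:fungus`$ssq,
               tolerance = 1e-10)
  expect_equal(sum(variation_table(comb)$variation_pct), 100, tolerance = 1e-6)
  expect_error(combine_effects(m, c("position", "position")), "itself")
  expect_error(combine_effects(m, c("position", "nope")), "unknown")
  ## combining with a zero effect changes nothing numerically
  m0 <- m
  m0$effects$fungus$values[] <- 0
  m0$effects$fungus$ssq <- 0
  comb0 <- combine_effects(m0, c("position", "fungus"))
  expect_equal(comb0$effects[["position+fungus"]]$values,
               m$effects$position$values)
})

test_that("planted fractions reproduce a decay-test variation structure", {
  exp <- make_stacked_experiment(seed = 12)
  Xc <- sweep(exp$spectra, 2, colMeans(exp$spectra))
  m <- asca_decompose(Xc, exp$design[c("position", "fungus", "replicate")])
  vt <- variation_table(m)
  expect_equal(sum(vt$variation_pct), 100, tolerance = 1e-6)
  fr <- setNames(vt$variation_pct, vt$effect)
  pl <- exp$planted$fractions
  expect_equal(unname(fr["position"]), unname(pl["position"]), tolerance = 0.03)
  expect_equal(unname(fr["position:fungus"]), unname(pl["position:fungus"]),
               tolerance = 0.2)
  comb <- combine_effects(m, c("position", "position:fungus"))
  expect_equal(comb$effects[["position+position:fungus"]]$ssq_fraction,
               unname(pl["position"] + pl["position:fungus"]), tolerance = 0.03)
})

test_that("permutation tests are seeded, bounded and detect dominant effects", {
  exp <- make_stacked_experiment(
    target_fractions = c(position = 80, fungus = 0, "position:fungus" = 0,
                         replicate = 5, noise = 15), seed = 31)
  Xc <- sweep(exp$spectra, 2, colMeans(exp$spectra))
  design <- exp$design[c("position", "fungus", "replicate")]
  p <- permutation_test(Xc, design, "position", n_perm = 199, seed = 5)
  expect_equal(p, 1 / 200)  # statistic exceeds every permutation
  expect_identical(p, permutation_test(Xc, design, "position",
                                       n_perm = 199, seed = 5))
  expect_error(permutation_test(Xc, design, "position", n_perm = 0), "n_perm")
  expect_error(permutation_test(Xc, design, "nope", n_perm = 10), "not found")
  ## the residual scheme also flags the dominant effect
  expect_equal(permutation_test(Xc, design, "position", n_perm = 99,
                                seed = 6, scheme = "residual"), 1 / 100)
})

test_that("effect SVD yields orthonormal, sign-fixed, rank-checked components", {
  set.seed(9)
  u <- rnorm(10); v <- rnorm(6)
  rank1 <- list(name = "r1", values = u %o% v)
  comp <- effect_svd(rank1, 1)
  expect_lt(max(abs(comp$scores %*% t(comp$loadings) - rank1$values)), 1e-10)
  expect_equal(crossprod(comp$loadings), diag(1), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_gt(comp$loadings[which.max(abs(comp$loadings)), 1], 0)
  expect_error(effect_svd(rank1, 2), "rank bound 1")
  M <- matrix(rnorm(12 * 8), 12)
  c2 <- effect_svd(list(name = "m", values = M), 3)
  expect_equal(crossprod(c2$loadings), diag(3), ignore_attr = TRUE,
               tolerance = 1e-10)
  ## truncated reconstruction equals the best rank-3 approximation
  sv <- svd(M)
  best <- sv$u[, 1:3] %*% diag(sv$d[1:3]) %*% t(sv$v[, 1:3])
  expect_lt(max(abs(c2$scores %*% t(c2$loadings) - best)), 1e-10)
})

test_that("residual projection adds E onto the loadings", {
  set.seed(10)
  M <- matrix(rnorm(10 * 5), 10)
  comp <- effect_svd(list(name = "m", values = M), 2)
  z <- project_residuals(comp, matrix(0, 10, 5))
  expect_equal(z$projected_scores, comp$scores)
  ## residual orthogonal to the loadings leaves scores untouched
  P <- comp$loadings
  E <- matrix(rnorm(10 * 5), 10)
  E_perp <- E - E %*% P %*% t(P)
  zp <- project_residuals(comp, E_perp)
  expect_lt(max(abs(zp$projected_scores - comp$scores)), 1e-10)
  zr <- project_residuals(comp, E)
  expect_equal(zr$projected_scores, comp$scores + E %*% P)
  expect_error(project_residuals(comp, matrix(0, 10, 4)), "band count")
})

test_that("the asca wrapper fills p-values and components deterministically", {
  exp <- make_stacked_experiment(seed = 2, config = phantom_config(n_bands = 40))
  Xc <- sweep(exp$spectra, 2, colMeans(exp$spectra))
  design <- exp$design[c("position", "fungus", "replicate")]
  m1 <- asca(Xc, design, n_perm = 49, seed = 7)
  m2 <- asca(Xc, design, n_perm = 49, seed = 7)
  expect_identical(m1$p_values, m2$p_values)
  expect_length(m1$p_values, 6)
  expect_lt(m1$p_values[["position"]], 0.05)
  expect_s3_class(m1$components$position, "asca_component")
  vt <- variation_table(m1)
  expect_true(is.na(vt$p_value[vt$effect == "residual"]))
  expect_false(any(is.na(vt$p_value[vt$effect != "residual"])))
})
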