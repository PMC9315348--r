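#' Generate a stacked-decay-test experiment of average spectra
#'
#' Emulates the average-spectrum table of a stacked-sample decay test:
#' a balanced full factorial of sample position (1-7, decay increasing
#' with position), fungal species (2 levels) and biological replicate
#' (5 levels), one SNV-scale spectrum per sample. The deterministic
#' part is built from known pieces that live exactly in the factorial
#' subspaces:
#'
#' * position: the SNV-transformed mixture spectrum at each position's
#'   mean decay fraction (earlywood/latewood weighted), centered over
#'   positions;
#' * fungus: a fixed loading-shaped contrast (normalized lignin-minus-
#'   carbohydrate direction) scaled by `fungus_effect_size`;
#' * position x fungus: a rank-one pattern (centered linear position
#'   score times the fungus contrast) scaled by
#'   `interaction_effect_size`;
#' * replicate: a seeded random spectral offset per replicate, centered
#'   over replicates, with SD `replicate_offset_sd`;
#' * residual: iid Gaussian noise with SD `noise_sd`.
#'
#' Because every piece is stored, the generator reports the exact
#' realized sum of squares of each planted effect; `target_fractions`
#' optionally rescales the pieces so the planted SSQ fractions hit
#' stated percentages exactly. The default targets reproduce the
#' variation structure typical of a brown-rot stacked decay test: a
#' dominant position effect, a small fungus effect, a moderate
#' position x fungus interaction and a minor replicate effect.
#'
#' @param config a [phantom_config()]; supplies wavelength grid, decay
#'   schedule and tissue proportions.
#' @param library a [component_library()].
#' @param n_replicates number of replicates (single positive integer;
#'   anything else is rejected because downstream ASCA requires a
#'   balanced design).
#' @param fungus_effect_size,interaction_effect_size,replicate_offset_sd,noise_sd
#'   raw scales of the planted pieces (SNV absorbance units).
#' @param fungi character vector of 2 species labels.
#' @param target_fractions optional named percentages (names among
#'   `position`, `fungus`, `position:fungus`, `replicate`, `noise`)
#'   summing to 100; each planted piece is rescaled so its realized SSQ
#'   fraction equals the target exactly. `NULL` keeps raw scales.
#' @param seed integer seed.
#' @return list with `spectra` (samples x bands matrix, SNV scale with
#'   grand spectrum included), `design` (data.frame: sample_id,
#'   position, fungus, replicate), `wavelengths`, and `planted` (list:
#'   `ssq` named vector incl. noise, `fractions` percentages,
#'   `pieces` the row-expanded planted matrices).
#' @export
make_stacked_experiment <- function(config = phantom_config(),
                                    library = component_library(),
                                    n_replicates = 5,
                                    fungus_effect_size = 0.2,
                                    interaction_effect_size = 0.2,
                                    replicate_offset_sd = 0.02,
                                    noise_sd = 0.05,
                                    fungi = c("C_puteana", "R_placenta"),
                                    target_fractions = c(
                                      "position" = 75.7, "fungus" = 4.3,
                                      "replicate" = 1.3,
                                      "position:fungus" = 8.1,
                                      "noise" = 10.6),
                                    seed = config$seed) {
  if (length(n_replicates) != 1L || n_replicates < 1 ||
      n_replicates != round(n_replicates))
    stop("balanced design required: n_replicates must be a single positive integer")
  if (length(fungi) != 2L) stop("balanced design required: exactly 2 fungus levels")
  set.seed(seed)
  wl <- phantom_wavelengths(config)
  S <- make_component_spectra(wl, library)
  dp <- config$decay_by_position
  positions <- dp$position
  np <- length(positions); nf <- 2L; nr <- as.integer(n_replicates)
  n <- np * nf * nr
  nb <- length(wl)

  ## position profiles: SNV mixture spectrum at the position-mean decay
  d_mean <- config$earlywood_fraction * dp$earlywood +
    (1 - config$earlywood_fraction) * dp$latewood
  cc <- config$base_carb * (1 - d_mean)
  prof <- snv(cc %o% S["carbohydrate", ] + (1 - cc) %o% S["lignin", ])
  grand <- colMeans(prof)
  pos_piece <- sweep(prof, 2, grand)              # np x nb, centered over p

  ## fungus contrast shape: lignin-vs-carbohydrate direction, unit norm
  v_f <- snv(matrix(S["lignin", ] - S["carbohydrate", ], 1))[1, ]
  v_f <- v_f / sqrt(sum(v_f^2))
  g_f <- c(-0.5, 0.5)                             # balanced contrast
  fun_piece <- fungus_effect_size * (g_f %o% v_f) # nf x nb

  ## interaction: rank-one, centered in both factors
  z_p <- positions - mean(positions)
  z_p <- z_p / sqrt(sum(z_p^2))
  v_pf <- S["carbohydrate", ] - mean(S["carbohydrate", ])
  v_pf <- v_pf - sum(v_pf * v_f) * v_f            # orthogonal to fungus shape
  v_pf <- v_pf / sqrt(sum(v_pf^2))
  int_cell <- interaction_effect_size *
    outer(z_p, g_f) %o% v_pf                      # np x nf x nb

  ## replicate offsets, centered across replicates
  rep_off <- matrix(rnorm(nr * nb, 0, replicate_offset_sd), nr, nb)
  rep_piece <- sweep(rep_off, 2, colMeans(rep_off))

  design <- expand.grid(replicate = seq_len(nr), fungus = fungi,
                        position = positions,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("position", "fungus", "replicate")]
  design$sample_id <- sprintf("p%d_%s_r%d", design$position,
                              substr(design$fungus, 1, 1), design$replicate)
  ip <- match(design$position, positions)
  jf <- match(design$fungus, fungi)
  kr <- design$replicate

  pieces <- list(
    "position"        = pos_piece[ip, , drop = FALSE],
    "fungus"          = fun_piece[jf, , drop = FALSE],
    "position:fungus" = matrix(int_cell[cbind(rep(ip, nb), rep(jf, nb),
                                              rep(seq_len(nb), each = n))],
                               n, nb),
    "replicate"       = rep_piece[kr, , drop = FALSE])
  noise <- matrix(rnorm(n * nb, 0, noise_sd), n, nb)

  if (!is.null(target_fractions)) {
    tf <- target_fractions
    bad <- setdiff(names(tf), c(names(pieces), "noise"))
    if (length(bad)) stop("unknown target_fractions names: ",
                          paste(bad, collapse = ", "))
    if (abs(sum(tf) - 100) > 1e-6) stop("target_fractions must sum to 100")
    cur <- c(vapply(pieces, function(m) sum(m^2), 0), noise = sum(noise^2))
    total <- sum(cur)
    for (nm in names(tf)) {
      want <- tf[[nm]] / 100 * total
      have <- cur[[nm]]
      if (want > 0 && have == 0)
        stop("cannot plant effect '", nm, "': its raw scale is zero")
      s <- if (have > 0) sqrt(want / have) else 0
      if (nm == "noise") noise <- noise * s else pieces[[nm]] <- pieces[[nm]] * s
    }
    ## pieces absent from the target keep their raw scale
  }

  X <- matrix(rep(grand, each = n), n, nb)
  for (m in pieces) X <- X + m
  X <- X + noise

  ssq <- c(vapply(pieces, function(m) sum(m^2), 0), noise = sum(noise^2))
  list(spectra = X, design = design, wavelengths = wl,
       planted = list(ssq = ssq, fractions = 100 * ssq / sum(ssq),
                      pieces = pieces))
}
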