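#' Pipeline run configuration
#'
#' Flat, serializable key-value configuration for [run_pipeline()].
#' Defaults mirror the analysis conventions of the rest of the package:
#' 3 x 3 median filter, 281 x 301 ROI (clamped to the phantom size),
#' 1,100-2,400 nm band range, 10,000 permutations, 4 PCA components,
#' 3 decay classes, correlation-metric assignment.
#'
#' @param ... overrides of any default field.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    outdir = "decaymap_run",
    stages = "simulate,preprocess,asca,pca,cluster,report",
    ## phantom geometry (desk scale)
    image_rows = 72L, image_cols = 72L, n_bands = 96L,
    ring_period = 16L, earlywood_fraction = 0.6, background_border = 6L,
    noise_sd = 20, scatter_gain_sd = 0.04, scatter_offset_sd = 0.008,
    ## preprocessing
    median_window = 3L, roi_height = 281L, roi_width = 301L,
    band_low = 1100, band_high = 2400, snv_on = "absorbance",
    mask_k_sd = 4,
    ## asca
    n_replicates = 5L, n_perm = 10000L,
    ## pca / clustering
    n_comp = 4L, outlier_k_sd = 4, k = 3L, metric = "correlation")
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration
#'
#' Configurations round-trip through a flat YAML file without loss.
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

config_hash <- function(config) {
  txt <- paste(names(config), vapply(config, function(v) paste(format(v), collapse = ","), ""),
               sep = "=", collapse = ";")
  ## small deterministic fingerprint (polynomial rolling hash)
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

pipeline_stages <- c("simulate", "preprocess", "asca", "pca", "cluster", "report")

#' Run the full decay-mapping pipeline
#'
#' Executes the requested stages in their fixed order
#' simulate -> preprocess -> asca -> pca -> cluster -> report, writing
#' every artifact (tables as CSV/JSON, the resolved configuration, a
#' log) under `config$outdir`. All randomness derives from
#' `config$seed`, so a rerun with the same configuration reproduces the
#' deterministic artifacts exactly.
#'
#' @param config a [run_config()].
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  stages <- trimws(strsplit(config$stages, ",")[[1]])
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  stages <- pipeline_stages[pipeline_stages %in% stages]  # enforce order
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "run.log")
  logline <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                               "\n", file = logf, append = TRUE)
  write_run_config(config, file.path(outdir, "config_resolved.yaml"))
  hash <- config_hash(config)
  logline("INFO run start; seed =", config$seed, "; config hash =", hash)

  pcfg <- phantom_config(image_rows = config$image_rows,
                         image_cols = config$image_cols,
                         n_bands = config$n_bands,
                         ring_period = config$ring_period,
                         earlywood_fraction = config$earlywood_fraction,
                         background_border = config$background_border,
                         noise_sd = config$noise_sd,
                         scatter_gain_sd = config$scatter_gain_sd,
                         scatter_offset_sd = config$scatter_offset_sd,
                         seed = config$seed)
  lib <- component_library()
  simdir <- file.path(outdir, "simulate")

  if ("simulate" %in% stages) {
    logline("INFO stage simulate")
    series <- make_phantom_series(pcfg, lib)
    write_phantom_series(series, simdir)
    exp <- make_stacked_experiment(pcfg, lib, n_replicates = config$n_replicates,
                                   seed = config$seed)
    sp <- as.data.frame(exp$spectra)
    names(sp) <- paste0("b", seq_len(ncol(sp)))
    write.csv(cbind(exp$design, sp),
              file.path(simdir, "average_spectra.csv"), row.names = FALSE)
    write.csv(exp$design, file.path(simdir, "design.csv"), row.names = FALSE)
    jsonlite::write_json(as.list(exp$planted$fractions),
                         file.path(simdir, "planted_fractions.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (any(c("preprocess", "asca", "pca", "cluster") %in% stages)) {
    if (!dir.exists(simdir))
      stop("inputs missing: run the simulate stage first (no ", simdir, ")")
  }

  predir <- file.path(outdir, "preprocess")
  if ("preprocess" %in% stages) {
    logline("INFO stage preprocess")
    dir.create(predir, showWarnings = FALSE)
    positions <- pcfg$decay_by_position$position
    pre <- list()
    for (p in positions) {
      base <- file.path(simdir, paste0("pos", p))
      cube <- read_envi(base)
      cube$meta$detector_full_scale <- pcfg$detector_full_scale
      cube$meta$position <- p
      white <- read_envi(paste0(base, "_white"))$values
      dark <- read_envi(paste0(base, "_dark"))$values
      pre[[paste0("pos", p)]] <-
        preprocess_cube(cube, white, dark,
                        roi_height = config$roi_height,
                        roi_width = config$roi_width,
                        band_low = config$band_low,
                        band_high = config$band_high,
                        window = config$median_window,
                        snv_on = config$snv_on,
                        mask_k_sd = config$mask_k_sd)
    }
    saveRDS(pre, file.path(predir, "preprocessed.rds"))
    avg <- do.call(rbind, lapply(names(pre), function(nm) {
      a <- pre[[nm]]$average
      data.frame(sample_id = nm, wavelength_nm = a$wavelengths,
                 value = a$values, stage = a$stage)
    }))
    write.csv(avg, file.path(predir, "roi_average_spectra.csv"),
              row.names = FALSE)
  }

  ascadir <- file.path(outdir, "asca")
  if ("asca" %in% stages) {
    logline("INFO stage asca")
    dir.create(ascadir, showWarnings = FALSE)
    exp <- read_stacked_csv(file.path(simdir, "average_spectra.csv"))
    X <- trim_bands(exp$spectra, config$band_low, config$band_high,
                    wavelengths = phantom_wavelengths(pcfg))
    Xc <- sweep(X, 2, colMeans(X))
    model <- asca(Xc, exp$design[c("position", "fungus", "replicate")],
                  n_perm = config$n_perm, seed = config$seed)
    model_c <- combine_effects(model, c("position", "position:fungus"))
    vt <- variation_table(model)
    write.csv(vt, file.path(ascadir, "variation_table.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, config_hash = hash,
           n_permutations = model$n_permutations,
           variation = setNames(as.list(vt$variation_pct), vt$effect),
           p_values = as.list(model$p_values),
           combined_position_fungus_pct =
             model_c$effects[["position+position:fungus"]]$ssq_fraction),
      file.path(ascadir, "asca_summary.json"), auto_unbox = TRUE, digits = NA)
    wl <- attr(X, "wavelengths")
    for (nm in names(model$components)) {
      comp <- model$components[[nm]]
      if (is.null(comp)) next
      write.csv(data.frame(wavelength_nm = wl, loading = comp$loadings[, 1]),
                file.path(ascadir, paste0("loadings_", gsub(":", "x", nm), ".csv")),
                row.names = FALSE)
      write.csv(data.frame(sample_id = exp$design$sample_id,
                           score = comp$scores[, 1],
                           projected_score = comp$projected_scores[, 1]),
                file.path(ascadir, paste0("scores_", gsub(":", "x", nm), ".csv")),
                row.names = FALSE)
    }
  }

  pcadir <- file.path(outdir, "pca")
  if ("pca" %in% stages) {
    logline("INFO stage pca")
    dir.create(pcadir, showWarnings = FALSE)
    pre <- readRDS(file.path(predir, "preprocessed.rds"))
    mos <- build_mosaic(lapply(pre, `[[`, "roi"),
                        masks = lapply(pre, `[[`, "mask"))
    fit0 <- mosaic_pca(mos, config$n_comp)
    res <- remove_extreme_pixels(fit0, mos, k_sd = config$outlier_k_sd)
    saveRDS(list(mosaic = res$mosaic, model = res$model),
            file.path(pcadir, "mosaic_pca.rds"))
    write.csv(cbind(wavelength_nm = mos$wavelengths,
                    as.data.frame(res$model$loadings)),
              file.path(pcadir, "loadings.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, config_hash = hash,
           variance_explained = res$model$variance_explained,
           n_excluded = sum(res$excluded)),
      file.path(pcadir, "variance.json"), auto_unbox = TRUE, digits = NA)
    maps <- score_images(res$model, res$mosaic)
    for (nm in names(maps))
      write.csv(maps[[nm]][, , 1], file.path(pcadir, paste0("pc1_", nm, ".csv")),
                row.names = FALSE)
  }

  cludir <- file.path(outdir, "cluster")
  if ("cluster" %in% stages) {
    logline("INFO stage cluster")
    dir.create(cludir, showWarnings = FALSE)
    st <- readRDS(file.path(pcadir, "mosaic_pca.rds"))
    cm <- kmeans_scores(st$model$scores, k = config$k, metric = config$metric)
    spectra <- class_mean_spectra(cm$labels, st$mosaic, k = config$k)
    write.csv(cbind(wavelength_nm = st$mosaic$wavelengths,
                    as.data.frame(t(spectra))),
              file.path(cludir, "class_spectra.csv"), row.names = FALSE)
    maps <- label_map(cm, st$mosaic)
    for (nm in names(maps))
      write.csv(maps[[nm]], file.path(cludir, paste0("labels_", nm, ".csv")),
                row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, config_hash = hash, sizes = cm$sizes,
           centroids = cm$centroids, converged = cm$converged,
           metric = cm$metric),
      file.path(cludir, "cluster_summary.json"), auto_unbox = TRUE, digits = NA)
  }

  if ("report" %in% stages) {
    logline("INFO stage report")
    report_run(outdir)
  }
  logline("INFO run complete")
  invisible(outdir)
}

read_stacked_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  meta_cols <- c("position", "fungus", "replicate", "sample_id")
  list(design = df[meta_cols],
       spectra = as.matrix(df[setdiff(names(df), meta_cols)]))
}

#' Summarize a pipeline run
#'
#' Collects the tables and summaries a finished (or partial) run left
#' behind into one human-readable `report.md`: ASCA variation table and
#' permutation p-values, PCA variance, cluster sizes, and the planted
#' ground-truth fractions when the run was synthetic. Missing stages
#' are reported as explicit gaps.
#'
#' @param run_dir a [run_pipeline()] output directory.
#' @return path of the written report, invisibly.
#' @export
report_run <- function(run_dir) {
  if (!dir.exists(run_dir) || !length(list.files(run_dir)))
    stop("not a pipeline run directory: ", run_dir)
  lines <- c("# decaymap pipeline report", "")
  cfgp <- file.path(run_dir, "config_resolved.yaml")
  if (file.exists(cfgp)) {
    cfg <- read_run_config(cfgp)
    lines <- c(lines, sprintf("seed: %s; config hash: %s", cfg$seed,
                              config_hash(cfg)), "")
  }
  section <- function(title, path, fmt) {
    if (file.exists(path)) c(paste("##", title), "", fmt(path), "")
    else c(paste("##", title), "", "(stage not run)", "")
  }
  lines <- c(lines,
    section("Simulated ground truth",
            file.path(run_dir, "simulate", "planted_fractions.json"),
            function(p) {
              fr <- jsonlite::read_json(p)
              sprintf("planted %s: %.2f%%", names(fr), unlist(fr))
            }),
    section("Preprocessing",
            file.path(run_dir, "preprocess", "roi_average_spectra.csv"),
            function(p) {
              df <- read.csv(p)
              sprintf("%d average spectra over %d bands (stage %s)",
                      length(unique(df$sample_id)),
                      length(unique(df$wavelength_nm)), df$stage[1])
            }),
    section("ASCA", file.path(run_dir, "asca", "asca_summary.json"),
            function(p) {
              s <- jsonlite::read_json(p)
              c(sprintf("%s: %.1f%% (p = %s)", names(s$variation),
                        unlist(s$variation),
                        vapply(names(s$variation), function(nm) {
                          pv <- s$p_values[[nm]]
                          if (is.null(pv)) "-" else format(pv, digits = 3)
                        }, "")),
                sprintf("combined position + position x fungus: %.1f%%",
                        s$combined_position_fungus_pct),
                sprintf("permutations per effect: %d", s$n_permutations))
            }),
    section("Mosaic PCA", file.path(run_dir, "pca", "variance.json"),
            function(p) {
              s <- jsonlite::read_json(p)
              c(sprintf("PC%d: %.1f%% of variation",
                        seq_along(s$variance_explained),
                        unlist(s$variance_explained)),
                sprintf("extreme pixels removed: %d", s$n_excluded))
            }),
    section("Clustering", file.path(run_dir, "cluster", "cluster_summary.json"),
            function(p) {
              s <- jsonlite::read_json(p)
              c(sprintf("class sizes: %s", paste(unlist(s$sizes), collapse = ", ")),
                sprintf("metric: %s; converged: %s", s$metric, s$converged))
            }))
  out <- file.path(run_dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}
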