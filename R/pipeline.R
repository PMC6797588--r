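#' Pipeline configuration
#'
#' One object driving the full analysis: data source (a synthetic season,
#' a directory of per-plot pixel CSVs, or a directory of per-plot NGB
#' TIFFs), the canopy threshold, histogram binning, the number of retained
#' components, and the PLS-R settings.
#'
#' In the two directory modes, pixel files must be named
#' `<genotype>_T<trial>_D<day>.csv` / `.tiff` (the convention used by
#' [write_season()]) and the directory must contain a `traits.csv` readable
#' by [read_trait_table()] unless `traits_csv` points elsewhere.
#'
#' @param mode `"synthetic"`, `"pixel-csv-dir"` or `"image-dir"`.
#' @param sim a [field_sim_config()] (synthetic mode; defaults to
#'   `field_sim_config(seed = seed)`).
#' @param input_dir input directory (directory modes).
#' @param traits_csv trait table path (directory modes; default
#'   `<input_dir>/traits.csv`).
#' @param year year label for directory-mode data.
#' @param threshold canopy/soil BNDVI cutoff (default 0.06).
#' @param n_bins histogram bins (default 999).
#' @param k_retained components retained by PCA (default 15).
#' @param components components used in correlation analyses (default 1:3).
#' @param plsr a [plsr_config()] (defaults to one seeded from `seed`).
#' @param trait_names traits analysed (default: all six).
#' @param out_dir output directory for persisted artifacts (`NULL` = do not
#'   write).
#' @param seed master seed.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "pixel-csv-dir", "image-dir"),
                            sim = NULL, input_dir = NULL, traits_csv = NULL,
                            year = "Y1", threshold = 0.06, n_bins = 999L,
                            k_retained = 15L, components = 1:3,
                            plsr = NULL,
                            trait_names = c("tassel_day", "silk_day",
                                            "yield_kg", "kernel_length",
                                            "kernel_width", "kernel_thickness"),
                            out_dir = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "synthetic") {
    if (is.null(sim)) sim <- field_sim_config(seed = seed)
  } else {
    if (is.null(input_dir) || !dir.exists(input_dir))
      stop("pipeline_config: input_dir must exist in mode ", mode)
    if (is.null(traits_csv)) traits_csv <- file.path(input_dir, "traits.csv")
    if (!file.exists(traits_csv))
      stop("pipeline_config: trait table not found: ", traits_csv)
  }
  if (is.null(plsr)) plsr <- plsr_config(seed = seed)
  structure(list(mode = mode, sim = sim, input_dir = input_dir,
                 traits_csv = traits_csv, year = year, threshold = threshold,
                 n_bins = as.integer(n_bins), k_retained = as.integer(k_retained),
                 components = components, plsr = plsr,
                 trait_names = trait_names, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

load_pixel_sets <- function(config) {
  if (config$mode == "synthetic") {
    season <- simulate_season(config$sim)
    return(list(pixel_sets = season$pixel_sets, traits = season$traits,
                season = season))
  }
  ext <- if (config$mode == "pixel-csv-dir") "csv" else "tiff?"
  files <- list.files(config$input_dir,
                      pattern = paste0("_T[0-9]+_D[0-9]+\\.", ext, "$"),
                      full.names = TRUE)
  if (length(files) == 0)
    stop("run_pipeline: no plot files matching <genotype>_T<trial>_D<day> in ",
         config$input_dir)
  sets <- lapply(files, function(path) {
    stem <- sub("\\.[a-z]+$", "", basename(path))
    parts <- regmatches(stem, regexec("^(.*)_T([0-9]+)_D([0-9]+)$", stem))[[1]]
    gid <- parts[2]; trial <- as.integer(parts[3]); day <- as.integer(parts[4])
    if (config$mode == "pixel-csv-dir") {
      read_pixel_csv(path, plot_id = sprintf("%s_T%d", gid, trial),
                     genotype_id = gid, trial = trial, flight_day = day,
                     year = config$year)
    } else {
      raster <- compute_bndvi(read_ngb_image(path, flight_day = day))
      v <- as.numeric(raster$values)
      plot_pixel_set(v[!is.na(v)], plot_id = sprintf("%s_T%d", gid, trial),
                     genotype_id = gid, trial = trial, flight_day = day,
                     year = config$year)
    }
  })
  names(sets) <- sub("\\.[a-z]+$", "", basename(files))
  list(pixel_sets = sets, traits = read_trait_table(config$traits_csv),
       season = NULL)
}

#' Run the full histogram-phenotyping analysis
#'
#' Executes every stage in order — ingest or simulate per-plot BNDVI pixel
#' sets, summarise mean canopy BNDVI, build 999-bin histogram phenotypes
#' and stack them into X, fit the PCA with back-projection sweeps, compute
#' date-resolved trait correlations and the low/high-yield group contrast,
#' detect pre-flowering dips, and fit the PLS-R hold-out prediction report
#' for both feature sources — persisting each intermediate as CSV when
#' `out_dir` is set, together with a JSON manifest recording the package
#' version, seed and configuration. Identical config and seed give
#' byte-identical numeric outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of class `pipeline_result` with all stage
#'   outputs (`traits`, `mean_bndvi`, `histogram_matrix`, `decomposition`,
#'   `sweeps`, `correlations`, `yield_groups`, `dips`, `plsr_report_pc`,
#'   `plsr_report_hist`, `feature_source_comparison`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "ingest"
  result <- tryCatch({
    data <- load_pixel_sets(config)
    message(sprintf("ingest: %d plot-date pixel sets, %d trait rows",
                    length(data$pixel_sets), nrow(data$traits)))

    stage <- "mean_bndvi"
    mb <- mean_bndvi_table(data$pixel_sets, config$threshold)
    message(sprintf("mean_bndvi: %d plot-dates, %d with no canopy",
                    nrow(mb), sum(is.na(mb$mean_bndvi))))

    stage <- "histograms"
    hists <- lapply(data$pixel_sets, build_histogram, n_bins = config$n_bins)
    hm <- stack_histograms(hists)
    dropped <- sum(vapply(hists, `[[`, 1, "n_pixels_dropped"))
    message(sprintf("histograms: X is %d x %d (%d pixels dropped as out of (0,1])",
                    nrow(hm$X), ncol(hm$X), dropped))

    stage <- "pca"
    decomp <- fit_pca(hm, k_retained = config$k_retained,
                      soil_threshold = config$threshold)
    sweeps <- lapply(intersect(config$components, seq_len(decomp$k_retained)),
                     function(pc) back_project_sweep(decomp, pc))
    message(sprintf("pca: %d components retained, %.1f%% variance explained",
                    decomp$k_retained, 100 * sum(decomp$variance_explained)))

    stage <- "correlations"
    pred <- predictor_table(decomp, components = config$components,
                            mean_bndvi = mb)
    correlations <- do.call(rbind, lapply(config$trait_names, function(tr)
      correlate_by_date(pred, data$traits, tr)))
    n_geno <- length(unique(data$traits$genotype_id))
    yield_groups <- if (n_geno >= 13)
      compare_yield_groups(pred, data$traits) else NULL
    dips <- detect_season_dips(mb, data$traits)
    message(sprintf("correlations: %d series rows; dips found for %d/%d genotype-years",
                    nrow(correlations), sum(dips$found), nrow(dips)))

    stage <- "plsr"
    reports_pc <- list(); reports_hist <- list()
    for (yr in unique(hm$row_index$year)) {
      feats_pc <- assemble_feature_matrix(decomp, yr, "pc_scores")
      feats_hist <- assemble_feature_matrix(hm, yr, "raw_histograms")
      reports_pc[[yr]] <- predict_traits_report(feats_pc, data$traits,
                                                config$plsr, config$trait_names)
      reports_hist[[yr]] <- predict_traits_report(feats_hist, data$traits,
                                                  config$plsr, config$trait_names)
    }
    comparison <- do.call(rbind, lapply(names(reports_pc), function(yr) {
      cmp <- compare_feature_sources(reports_pc[[yr]], reports_hist[[yr]])
      cmp$year <- yr
      cmp
    }))
    message("plsr: reports complete for both feature sources")

    list(config = config, traits = data$traits, mean_bndvi = mb,
         histogram_matrix = hm, decomposition = decomp, sweeps = sweeps,
         correlations = correlations, yield_groups = yield_groups,
         dips = dips,
         plsr_report_pc = do.call(rbind, reports_pc),
         plsr_report_hist = do.call(rbind, reports_hist),
         feature_source_comparison = comparison)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  class(result) <- "pipeline_result"
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  invisible(result)
}

write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  utils::write.csv(as.data.frame(result$traits),
                   file.path(out_dir, "traits.csv"), row.names = FALSE)
  utils::write.csv(result$mean_bndvi,
                   file.path(out_dir, "mean_bndvi.csv"), row.names = FALSE)
  write_histogram_matrix(result$histogram_matrix,
                         file.path(out_dir, "histograms"))
  write_decomposition(result$decomposition, file.path(out_dir, "pca"))
  for (sw in result$sweeps) {
    m <- cbind(score = sw$sweep_scores, sw$model_histograms)
    write_matrix_csv(m, file.path(out_dir,
                                  sprintf("sweep_pc%d.csv", sw$pc_index)))
  }
  utils::write.csv(result$correlations,
                   file.path(out_dir, "correlations.csv"), row.names = FALSE)
  if (!is.null(result$yield_groups))
    utils::write.csv(result$yield_groups,
                     file.path(out_dir, "yield_groups.csv"), row.names = FALSE)
  utils::write.csv(result$dips, file.path(out_dir, "dips.csv"),
                   row.names = FALSE)
  utils::write.csv(result$plsr_report_pc,
                   file.path(out_dir, "plsr_report_pc_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(result$plsr_report_hist,
                   file.path(out_dir, "plsr_report_raw_histograms.csv"),
                   row.names = FALSE)
  utils::write.csv(result$feature_source_comparison,
                   file.path(out_dir, "feature_source_comparison.csv"),
                   row.names = FALSE)
  manifest <- list(
    package = "uavphenome",
    version = as.character(utils::packageVersion("uavphenome")),
    seed = cfg$seed,
    mode = cfg$mode,
    threshold = cfg$threshold,
    n_bins = cfg$n_bins,
    k_retained = cfg$k_retained,
    config_hash = sub_seed(0, paste(utils::capture.output(utils::str(cfg)),
                                    collapse = "\n")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
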