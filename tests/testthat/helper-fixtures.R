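# Small, fast study configurations shared across test files.
# Seasons are cached per options-signature so expensive simulations run once.

.fixture_cache <- new.env(parent = emptyenv())

small_config <- function(n_genotypes = 8, pixels_per_plot = 1500, seed = 11,
                         ...) {
  field_sim_config(n_genotypes = n_genotypes,
                   pixels_per_plot = pixels_per_plot, seed = seed, ...)
}

cached_season <- function(key, config) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- simulate_season(config)
  .fixture_cache[[key]]
}

small_season <- function() {
  cached_season("small", small_config())
}

# analysis stack on the small season, computed once
small_analysis <- function() {
  if (is.null(.fixture_cache$small_analysis)) {
    season <- small_season()
    hists <- lapply(season$pixel_sets, build_histogram)
    hm <- stack_histograms(hists)
    decomp <- fit_pca(hm, k_retained = 10)
    .fixture_cache$small_analysis <-
      list(season = season, hm = hm, decomp = decomp,
           mb = mean_bndvi_table(season$pixel_sets))
  }
  .fixture_cache$small_analysis
}

# minimal hand-built decomposition for bookkeeping tests
toy_decomposition <- function(scores, row_index, m = 4) {
  structure(list(mean_histogram = rep(1 / m, m),
                 eigenvectors = diag(ncol(scores))[, seq_len(m), drop = FALSE],
                 eigenvalues = rep(1, ncol(scores)),
                 variance_explained = rep(1 / ncol(scores), ncol(scores)),
                 variance_explained_all = rep(1 / ncol(scores), ncol(scores)),
                 scores = scores, k_retained = ncol(scores),
                 row_index = row_index),
            class = "histogram_decomposition")
}

toy_traits <- function(genotype_id, trial = 1L, year = "Y1", tassel_day = 60,
                       silk_day = tassel_day + 2, yield_kg = 15,
                       kernel_length = 10, kernel_width = 8,
                       kernel_thickness = 6) {
  trait_table(data.frame(genotype_id = genotype_id, trial = trial,
                         year = year, tassel_day = tassel_day,
                         silk_day = silk_day, yield_kg = yield_kg,
                         kernel_length = kernel_length,
                         kernel_width = kernel_width,
                         kernel_thickness = kernel_thickness,
                         stringsAsFactors = FALSE))
}
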