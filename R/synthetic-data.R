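#' Configuration for the synthetic field-season generator
#'
#' Bundles and validates every parameter of the generative model: a maize
#' trial of `n_genotypes` hybrids grown in `n_trials` replicated plots,
#' overflown on `flight_days`, with each plot imaged as `pixels_per_plot`
#' BNDVI pixel values drawn from a two-component soil/canopy Gaussian
#' mixture. The canopy fraction follows a logistic ground-cover curve, the
#' canopy mean BNDVI rises to a genotype-specific peak, dips transiently a
#' few days before flowering (tassel material entering the scene), and then
#' declines with senescence at a rate reduced by a stay-green latent factor
#' that also drives grain yield.
#'
#' @param n_genotypes number of genotypes (default 25).
#' @param n_trials number of replicated trials per genotype (default 2).
#' @param flight_days strictly increasing integer days-of-season of the
#'   flights (default weekly, day 30 to 93).
#' @param pixels_per_plot pixels simulated per plot image (default 20000;
#'   real plots have ~2e5, scaled down for speed).
#' @param soil_mean,soil_sd Gaussian parameters of the bare-soil BNDVI
#'   component; `soil_mean + 2*soil_sd` should sit near or below the 0.06
#'   canopy threshold so soil and canopy are well separated.
#' @param canopy_sd within-plot spread of canopy BNDVI.
#' @param trait_noise_sd named vector of genotype-level trait noise standard
#'   deviations (`tassel_day`, `silk_day`, `yield_kg`, `kernel_length`,
#'   `kernel_width`, `kernel_thickness`) — variation shared by both trial
#'   replicates of a genotype.
#' @param plot_noise_sd named vector (same names) of plot-level measurement
#'   noise applied independently per trial replicate. For grain yield this
#'   term dominates (single-plot combine weights and field heterogeneity),
#'   which keeps yield prediction in the moderate regime reported for field
#'   data; flowering dates are scored much more precisely.
#' @param flowering_window integer range (lo, hi) of days over which genotype
#'   flowering dates are spread.
#' @param dip_depth depth (BNDVI units) of the pre-flowering dip.
#' @param dip_lead_days days by which the dip centre precedes flowering.
#' @param dip_sd_days temporal width (Gaussian sd, days) of the dip.
#' @param senescence_rate baseline post-peak BNDVI decline per day.
#' @param stay_green_gain maximal fractional reduction of the senescence rate
#'   for the most stay-green genotype (0 disables the yield coupling).
#' @param greenness_yield_weight,staygreen_yield_weight kg/plot contributed
#'   to yield per unit of the early-greenness and stay-green latent factors.
#' @param yield_base mean grain yield, kg/plot.
#' @param green0 canopy BNDVI of the youngest identifiable plants.
#' @param peak_base,peak_range mean and half-range of genotype peak canopy
#'   greenness; peak = peak_base + peak_range * latent_green.
#' @param closure_day_mean,closure_day_sd distribution of the day at which
#'   canopy cover reaches 50%.
#' @param closure_rate logistic steepness of canopy closure (per day).
#' @param greenup_lead_days,greenup_rate timing and steepness of the canopy
#'   pixels' main greenness rise, which precedes canopy closure (midpoint
#'   `closure_day - greenup_lead_days`) and is steeper than it: individual
#'   plant pixels approach peak greenness early, while the plot-mean BNDVI
#'   rise is driven mostly by ground cover. This keeps the canopy-mode
#'   location recoverable by the histogram decomposition even when
#'   early-season canopy mass is small.
#' @param late_green_share,late_green_rate,late_green_lead_days a second,
#'   slow greening component (fraction `late_green_share` of the rise,
#'   logistic midpoint `flowering_day - late_green_lead_days`) that carries
#'   canopy greenness to its peak during the flowering period and gives the
#'   component scores their flowering-locked inflection.
#' @param peak_offset_days days after flowering at which greenness peaks and
#'   senescent decline begins.
#' @param plot_effect_sd standard deviation (BNDVI units) of a plot-level
#'   canopy-greenness offset, drawn once per plot (genotype x trial) and
#'   held constant through the season: field-position effects (soil patches,
#'   moisture) that make replicate plots of the same genotype differ. This
#'   is why trials are replicated; without it, replicate plots would be
#'   unrealistically identical up to pixel sampling noise.
#' @param seed master integer seed; every random draw is sub-seeded from it.
#' @param year label attached to all outputs.
#' @return an object of class `field_sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- field_sim_config(n_genotypes = 4, pixels_per_plot = 500)
#' str(cfg[c("n_genotypes", "flight_days")])
field_sim_config <- function(n_genotypes = 25,
                             n_trials = 2,
                             flight_days = seq(30L, 93L, by = 7L),
                             pixels_per_plot = 20000,
                             soil_mean = 0.0,
                             soil_sd = 0.025,
                             canopy_sd = 0.08,
                             trait_noise_sd = c(tassel_day = 0.3,
                                                silk_day = 0.3,
                                                yield_kg = 1.0,
                                                kernel_length = 0.25,
                                                kernel_width = 0.3,
                                                kernel_thickness = 0.12),
                             plot_noise_sd = c(tassel_day = 0.4,
                                               silk_day = 0.4,
                                               yield_kg = 4.5,
                                               kernel_length = 0.15,
                                               kernel_width = 0.15,
                                               kernel_thickness = 0.08),
                             flowering_window = c(58L, 66L),
                             dip_depth = 0.04,
                             dip_lead_days = 3,
                             dip_sd_days = 2,
                             senescence_rate = 0.012,
                             stay_green_gain = 0.6,
                             greenness_yield_weight = 0.5,
                             staygreen_yield_weight = 7.5,
                             yield_base = 19,
                             green0 = 0.45,
                             peak_base = 0.62,
                             peak_range = 0.04,
                             closure_day_mean = 42,
                             closure_day_sd = 2,
                             closure_rate = 0.3,
                             greenup_lead_days = 8,
                             greenup_rate = 0.45,
                             late_green_share = 0.15,
                             late_green_rate = 0.2,
                             late_green_lead_days = 5,
                             peak_offset_days = 2,
                             plot_effect_sd = 0.02,
                             seed = 1L,
                             year = "Y1") {
  cfg <- as.list(environment())
  class(cfg) <- "field_sim_config"
  validate_field_sim_config(cfg)
  cfg
}

validate_field_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "field_sim_config"))
  if (cfg$n_genotypes < 1 || cfg$n_trials < 1)
    stop("field_sim_config: n_genotypes and n_trials must be >= 1")
  if (length(cfg$flight_days) < 1 || any(diff(cfg$flight_days) <= 0))
    stop("field_sim_config: flight_days must be strictly increasing")
  if (cfg$pixels_per_plot < 100)
    stop("field_sim_config: pixels_per_plot must be >= 100")
  needed <- c("tassel_day", "silk_day", "yield_kg", "kernel_length",
              "kernel_width", "kernel_thickness")
  if (!all(needed %in% names(cfg$trait_noise_sd)) ||
      !all(needed %in% names(cfg$plot_noise_sd)))
    stop("field_sim_config: trait_noise_sd and plot_noise_sd must name all six traits")
  if (any(cfg$trait_noise_sd < 0) || any(cfg$plot_noise_sd < 0))
    stop("field_sim_config: negative noise sd")
  if (cfg$soil_mean + 2 * cfg$soil_sd > 0.06)
    warning("soil_mean + 2*soil_sd exceeds the 0.06 canopy threshold; ",
            "soil and canopy pixels will overlap substantially")
  if (cfg$peak_base - cfg$peak_range - cfg$dip_depth <= 0.06)
    stop("field_sim_config: dip can push canopy BNDVI below the 0.06 ",
         "soil threshold (peak_base - peak_range - dip_depth <= 0.06)")
  fw <- cfg$flowering_window
  if (length(fw) != 2 || fw[1] > fw[2])
    stop("field_sim_config: flowering_window must be (lo, hi) with lo <= hi")
  if (fw[1] < min(cfg$flight_days) || fw[2] > max(cfg$flight_days))
    stop("field_sim_config: flowering_window must lie within flight_days")
  invisible(cfg)
}

#' Draw genotype specifications for a simulated trial
#'
#' Creates one row per genotype with flowering date, canopy-dynamics
#' parameters and end-of-season traits. Two independent latent factors drive
#' the trait structure: `latent_green` (early/peak canopy greenness) and
#' `latent_staygreen` (persistence of greenness after flowering, i.e. a
#' reduced senescence rate). Grain yield increases with both latents plus
#' independent noise, so yield varies more than two-fold across genotypes
#' and its strongest aerial signature appears after flowering. Kernel length
#' is positively, and kernel thickness negatively, coupled to the stay-green
#' latent; kernel width is uncoupled.
#'
#' Flowering days are spread over the configured contiguous window; when
#' there are at least as many genotypes as days in the window, every day in
#' the window is represented.
#'
#' @param config a [field_sim_config()].
#' @return a `data.frame` of class `genotype_spec`, one row per genotype.
#' @export
simulate_genotypes <- function(config) {
  validate_field_sim_config(config)
  n <- config$n_genotypes
  with_seed(sub_seed(config$seed, "genotypes"), {
    latent_green <- stats::runif(n, -1, 1)
    latent_staygreen <- stats::runif(n, -1, 1)
    fw <- as.integer(config$flowering_window)
    days <- fw[1]:fw[2]
    flowering_day <- if (n >= length(days)) {
      sample(c(days, sample(days, n - length(days), replace = TRUE)))
    } else {
      sort(sample(days, n))
    }
    nsd <- config$trait_noise_sd
    yield <- config$yield_base +
      config$greenness_yield_weight * latent_green +
      config$staygreen_yield_weight * latent_staygreen +
      stats::rnorm(n, 0, nsd[["yield_kg"]])
    spec <- data.frame(
      genotype_id = sprintf("G%02d", seq_len(n)),
      flowering_day = flowering_day,
      silk_offset_days = sample(1:3, n, replace = TRUE),
      yield_kg_per_plot = pmax(yield, 1),
      kernel_length_mm = pmax(10 + 1.0 * latent_staygreen +
                                stats::rnorm(n, 0, nsd[["kernel_length"]]), 1),
      kernel_width_mm = pmax(8 + stats::rnorm(n, 0, nsd[["kernel_width"]]), 1),
      kernel_thickness_mm = pmax(6 - 0.5 * latent_staygreen +
                                   stats::rnorm(n, 0, nsd[["kernel_thickness"]]), 1),
      closure_day = stats::rnorm(n, config$closure_day_mean, config$closure_day_sd),
      closure_rate = config$closure_rate,
      peak_greenness = config$peak_base + config$peak_range * latent_green,
      dip_depth = config$dip_depth,
      dip_lead_days = config$dip_lead_days,
      senescence_rate = config$senescence_rate *
        (1 - config$stay_green_gain * (latent_staygreen + 1) / 2),
      stay_green_gain = config$stay_green_gain,
      latent_green = latent_green,
      latent_staygreen = latent_staygreen,
      stringsAsFactors = FALSE
    )
    class(spec) <- c("genotype_spec", "data.frame")
    spec
  })
}

#' Canopy ground-cover fraction at a given day
#'
#' Logistic canopy-closure curve: the fraction of the plot covered by plant
#' material, reaching 0.5 at `closure_day`.
#'
#' @param spec one row of a [simulate_genotypes()] table.
#' @param day day(s) of season.
#' @return fraction(s) in (0, 1), non-decreasing in `day`.
#' @export
canopy_fraction <- function(spec, day) {
  stats::plogis((day - spec$closure_day) * spec$closure_rate)
}

#' Mean canopy BNDVI at a given day
#'
#' Seasonal trajectory of a genotype's canopy greenness: a steep early
#' logistic rise from the seedling baseline (plant pixels green up ahead of
#' canopy closure) plus a small slow greening component anchored a few days
#' before flowering that carries greenness to its peak during the flowering
#' period; a Gaussian-in-time dip centred `dip_lead_days` before flowering;
#' and a linear senescent decline beginning shortly after flowering at the
#' genotype's (stay-green adjusted) senescence rate. Floored at 0.08, just
#' above the soil threshold.
#'
#' @inheritParams canopy_fraction
#' @param config a [field_sim_config()] (supplies green-up baseline, timing
#'   and the peak timing offset).
#' @return mean canopy BNDVI value(s).
#' @export
canopy_mean_bndvi <- function(spec, day, config) {
  rise <- (1 - config$late_green_share) *
    stats::plogis((day - (spec$closure_day - config$greenup_lead_days)) *
                    config$greenup_rate) +
    config$late_green_share *
    stats::plogis((day - (spec$flowering_day - config$late_green_lead_days)) *
                    config$late_green_rate)
  mu <- config$green0 + (spec$peak_greenness - config$green0) * rise
  dip_centre <- spec$flowering_day - spec$dip_lead_days
  dip <- spec$dip_depth * exp(-0.5 * ((day - dip_centre) / config$dip_sd_days)^2)
  peak_day <- spec$flowering_day + config$peak_offset_days
  decline <- spec$senescence_rate * pmax(0, day - peak_day)
  pmax(mu - dip - decline, 0.08)
}

#' Simulate the BNDVI pixel values of one plot on one flight date
#'
#' Draws `pixels_per_plot` values from the soil/canopy mixture: a fraction
#' `canopy_fraction(spec, day)` of the pixels (rounded to a count) from
#' `Normal(canopy_mean_bndvi(spec, day, config) + plot offset, canopy_sd)`
#' and the rest from `Normal(soil_mean, soil_sd)`, all clipped to [-1, 1],
#' where the plot offset is the season-constant field-position effect of
#' this genotype x trial plot (see `plot_effect_sd`). Each plot-date gets
#' its own sub-seed, so the same plot-date can be regenerated independently
#' of the rest of the season.
#'
#' @param spec one row of a [simulate_genotypes()] table.
#' @param day flight day-of-season.
#' @param config a [field_sim_config()].
#' @param trial trial index (replicates differ only by pixel/trait noise).
#' @return an object of class `plot_pixel_set`: a list with `bndvi_values`
#'   and plot metadata.
#' @export
simulate_plot_pixels <- function(spec, day, config, trial = 1L) {
  validate_field_sim_config(config)
  stopifnot(nrow(spec) == 1)
  n <- config$pixels_per_plot
  f <- canopy_fraction(spec, day)
  # season-constant plot-level greenness offset (field-position effect);
  # sub-seeded by plot only, so every flight date of a plot shares it
  offset <- with_seed(sub_seed(config$seed, "ploteffect", spec$genotype_id,
                               trial),
                      stats::rnorm(1, 0, config$plot_effect_sd))
  mu <- canopy_mean_bndvi(spec, day, config) + offset
  n_can <- round(f * n)
  with_seed(sub_seed(config$seed, "pixels", spec$genotype_id, trial, day), {
    vals <- c(stats::rnorm(n_can, mu, config$canopy_sd),
              stats::rnorm(n - n_can, config$soil_mean, config$soil_sd))
    plot_pixel_set(pmin(pmax(vals, -1), 1),
                   plot_id = sprintf("%s_T%d", spec$genotype_id, trial),
                   genotype_id = spec$genotype_id,
                   trial = as.integer(trial),
                   flight_day = day,
                   year = config$year)
  })
}

#' Construct a per-plot pixel set
#'
#' The raw phenotype material of one plot on one flight date: a vector of
#' BNDVI values in [-1, 1] plus plot metadata.
#'
#' @param bndvi_values numeric vector in [-1, 1], non-empty.
#' @param plot_id,genotype_id,trial,flight_day,year plot metadata.
#' @return an object of class `plot_pixel_set`.
#' @export
plot_pixel_set <- function(bndvi_values, plot_id, genotype_id = plot_id,
                           trial = 1L, flight_day = NA_integer_, year = "Y1") {
  if (length(bndvi_values) == 0) stop("plot_pixel_set: empty pixel vector")
  if (any(!is.finite(bndvi_values)) ||
      any(bndvi_values < -1 | bndvi_values > 1))
    stop("plot_pixel_set: BNDVI values must be finite and in [-1, 1]")
  structure(list(bndvi_values = as.numeric(bndvi_values),
                 plot_id = plot_id, genotype_id = genotype_id,
                 trial = as.integer(trial), flight_day = flight_day,
                 year = year),
            class = "plot_pixel_set")
}

#' @export
print.plot_pixel_set <- function(x, ...) {
  cat(sprintf("<plot_pixel_set> %s (genotype %s, trial %d, day %s, %s): %d pixels, mean BNDVI %.3f\n",
              x$plot_id, x$genotype_id, x$trial,
              format(x$flight_day), x$year,
              length(x$bndvi_values), mean(x$bndvi_values)))
  invisible(x)
}

#' Simulate a complete field season
#'
#' Generates genotypes, then one [plot_pixel_set] per genotype x trial x
#' flight day, plus the matching trait table (one row per genotype x trial;
#' trial replicates share the genotype specification but receive independent
#' pixel noise and independent trait measurement noise).
#'
#' @param config a [field_sim_config()].
#' @param genotypes optionally, a pre-built [simulate_genotypes()] table.
#' @return an object of class `field_season`: a list with `pixel_sets`
#'   (named list of `plot_pixel_set`), `traits` (a [trait_table()]),
#'   `genotypes` and `config`.
#' @export
simulate_season <- function(config, genotypes = NULL) {
  validate_field_sim_config(config)
  if (is.null(genotypes)) genotypes <- simulate_genotypes(config)
  n_g <- nrow(genotypes)
  sets <- vector("list", n_g * config$n_trials * length(config$flight_days))
  nm <- character(length(sets))
  i <- 0L
  for (g in seq_len(n_g)) {
    spec <- genotypes[g, , drop = FALSE]
    for (trial in seq_len(config$n_trials)) {
      for (day in config$flight_days) {
        i <- i + 1L
        sets[[i]] <- simulate_plot_pixels(spec, day, config, trial)
        nm[i] <- sprintf("%s_T%d_D%03d", spec$genotype_id, trial, day)
      }
    }
  }
  names(sets) <- nm

  psd <- config$plot_noise_sd
  rows <- expand.grid(trial = seq_len(config$n_trials),
                      g = seq_len(n_g), KEEP.OUT.ATTRS = FALSE)
  traits <- with_seed(sub_seed(config$seed, "traits"), {
    tassel <- genotypes$flowering_day[rows$g] +
      stats::rnorm(nrow(rows), 0, psd[["tassel_day"]])
    data.frame(
      genotype_id = genotypes$genotype_id[rows$g],
      trial = rows$trial,
      year = config$year,
      tassel_day = tassel,
      silk_day = tassel + genotypes$silk_offset_days[rows$g] +
        stats::rnorm(nrow(rows), 0, psd[["silk_day"]]),
      yield_kg = pmax(genotypes$yield_kg_per_plot[rows$g] +
        stats::rnorm(nrow(rows), 0, psd[["yield_kg"]]), 0.1),
      kernel_length = genotypes$kernel_length_mm[rows$g] +
        stats::rnorm(nrow(rows), 0, psd[["kernel_length"]]),
      kernel_width = genotypes$kernel_width_mm[rows$g] +
        stats::rnorm(nrow(rows), 0, psd[["kernel_width"]]),
      kernel_thickness = genotypes$kernel_thickness_mm[rows$g] +
        stats::rnorm(nrow(rows), 0, psd[["kernel_thickness"]]),
      stringsAsFactors = FALSE
    )
  })
  traits <- trait_table(traits)

  structure(list(pixel_sets = sets, traits = traits,
                 genotypes = genotypes, config = config),
            class = "field_season")
}

#' @export
print.field_season <- function(x, ...) {
  cat(sprintf("<field_season> %s: %d genotypes x %d trials x %d flights (%d pixel sets, %d px/plot)\n",
              x$config$year, nrow(x$genotypes), x$config$n_trials,
              length(x$config$flight_days), length(x$pixel_sets),
              x$config$pixels_per_plot))
  invisible(x)
}

#' Write a simulated season to disk
#'
#' Persists each plot-date pixel set either as a one-column CSV of BNDVI
#' values or as a 3-channel 16-bit NGB TIFF whose NIR and blue channels
#' invert the BNDVI definition (so the vegetation-index module can be
#' exercised on image input), plus the trait table as CSV.
#'
#' @param season a [simulate_season()] result.
#' @param dir output directory (created if absent).
#' @param format `"csv"` or `"tiff"` for the pixel data.
#' @return invisibly, the vector of files written.
#' @export
write_season <- function(season, dir, format = c("csv", "tiff")) {
  format <- match.arg(format)
  stopifnot(inherits(season, "field_season"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(season$pixel_sets)) {
    ps <- season$pixel_sets[[nm]]
    if (format == "csv") {
      path <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(data.frame(bndvi = ps$bndvi_values), path,
                       row.names = FALSE)
    } else {
      path <- file.path(dir, paste0(nm, ".tiff"))
      write_ngb_tiff(ps$bndvi_values, path)
    }
    files <- c(files, path)
  }
  tpath <- file.path(dir, "traits.csv")
  utils::write.csv(as.data.frame(season$traits), tpath, row.names = FALSE)
  invisible(c(files, tpath))
}
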