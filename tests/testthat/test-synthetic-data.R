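test_that("config validation rejects malformed study designs", {
  expect_error(field_sim_config(flight_days = c(40, 40, 50)), "increasing")
  expect_error(field_sim_config(pixels_per_plot = 10), "100")
  expect_error(field_sim_config(flowering_window = c(10, 20)),
               "flowering_window")
  expect_error(field_sim_config(dip_depth = 0.6), "0.06")
  expect_warning(field_sim_config(soil_mean = 0.05), "threshold")
})

test_that("simulate_genotypes spreads flowering over the window and yields vary >= two-fold", {
  cfg <- small_config(n_genotypes = 25)
  spec <- simulate_genotypes(cfg)
  expect_equal(nrow(spec), 25)
  expect_equal(range(spec$flowering_day), cfg$flowering_window)
  expect_true(all(spec$flowering_day >= min(cfg$flight_days) &
                    spec$flowering_day <= max(cfg$flight_days)))
  expect_gt(max(spec$yield_kg_per_plot) / min(spec$yield_kg_per_plot), 2)
  expect_true(all(spec$yield_kg_per_plot > 0))
  expect_true(all(spec[, grep("_mm$", names(spec))] > 0))
  expect_true(all(spec$peak_greenness - spec$dip_depth > 0.06))
})

test_that("noise-free yield rank order follows the latent greenness-persistence factor", {
  cfg <- small_config(n_genotypes = 12)
  cfg$trait_noise_sd[["yield_kg"]] <- 0
  spec <- simulate_genotypes(cfg)
  latent <- cfg$greenness_yield_weight * spec$latent_green +
    cfg$staygreen_yield_weight * spec$latent_staygreen
  expect_equal(order(spec$yield_kg_per_plot), order(latent))
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- small_config(n_genotypes = 4, pixels_per_plot = 400)
  s1 <- simulate_season(cfg)
  s2 <- simulate_season(cfg)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$traits, s2$traits)
  expect_identical(s1$pixel_sets[[5]]$bndvi_values,
                   s2$pixel_sets[[5]]$bndvi_values)
  # plot-dates are independently re-generable out of season context
  ps <- simulate_plot_pixels(s1$genotypes[2, ], cfg$flight_days[3], cfg,
                             trial = 2)
  key <- sprintf("%s_T2_D%03d", s1$genotypes$genotype_id[2],
                 cfg$flight_days[3])
  expect_identical(ps$bndvi_values, s1$pixel_sets[[key]]$bndvi_values)
})

test_that("early-season plots are soil-dominated and all values lie in [-1, 1]", {
  cfg <- small_config(n_genotypes = 2, pixels_per_plot = 3000)
  spec <- simulate_genotypes(cfg)[1, ]
  ps <- simulate_plot_pixels(spec, day = 30, cfg)
  expect_true(all(ps$bndvi_values >= -1 & ps$bndvi_values <= 1))
  expect_gt(mean(ps$bndvi_values < 0.06), 0.9)
})

test_that("mid-season canopy pixels match the analytic mixture mean", {
  cfg <- small_config(n_genotypes = 2, pixels_per_plot = 20000,
                      plot_effect_sd = 0)  # isolate the mixture core
  cfg$dip_depth <- 0
  spec <- simulate_genotypes(cfg)[1, ]
  day <- spec$flowering_day  # canopy closed, dip disabled, no senescence yet
  f <- canopy_fraction(spec, day)
  expect_gt(f, 0.99)
  mu <- canopy_mean_bndvi(spec, day, cfg)
  ps <- simulate_plot_pixels(spec, day, cfg)
  canopy <- ps$bndvi_values[ps$bndvi_values >= 0.06]
  se <- cfg$canopy_sd / sqrt(length(canopy))
  expect_lt(abs(mean(canopy) - mu), 3 * se)
})

test_that("the pre-flowering dip lowers mean BNDVI by ~ dip_depth * canopy fraction", {
  cfg <- small_config(n_genotypes = 2, pixels_per_plot = 50000)
  cfg_nodip <- cfg
  cfg_nodip$dip_depth <- 0
  spec <- simulate_genotypes(cfg)[1, ]
  spec_nodip <- spec
  spec_nodip$dip_depth <- 0
  day <- spec$flowering_day - spec$dip_lead_days
  f <- canopy_fraction(spec, day)
  with_dip <- simulate_plot_pixels(spec, day, cfg)
  control <- simulate_plot_pixels(spec_nodip, day, cfg_nodip)
  diff_obs <- mean(control$bndvi_values) - mean(with_dip$bndvi_values)
  se <- sqrt(2) * cfg$canopy_sd / sqrt(cfg$pixels_per_plot)
  expect_lt(abs(diff_obs - cfg$dip_depth * f), 4 * se)
})

test_that("season output shapes and the grand-mean seasonal curve are as designed", {
  cfg <- field_sim_config(n_genotypes = 10, n_trials = 2,
                          flight_days = seq(30, 96, by = 6),
                          pixels_per_plot = 1000, seed = 3)
  season <- simulate_season(cfg)
  expect_length(season$pixel_sets, 10 * 2 * 12)
  expect_equal(nrow(season$traits), 20)
  mb <- mean_bndvi_table(season$pixel_sets)
  curve <- tapply(mb$mean_bndvi, mb$flight_day, mean, na.rm = TRUE)
  days <- as.numeric(names(curve))
  peak_day <- days[which.max(curve)]
  fw <- range(season$genotypes$flowering_day)
  # the canopy mean plateaus after green-up and is suppressed by the
  # pre-flowering dip, so the argmax can sit anywhere from late green-up
  # through the flowering period
  expect_gte(peak_day, fw[1] - 14)
  expect_lte(peak_day, fw[2] + cfg$peak_offset_days + 6)
  expect_gt(curve[[which(days == 60)]], curve[[1]])  # rises
  expect_lt(tail(curve, 1), max(curve))              # declines
})

test_that("canopy fraction is non-decreasing in day", {
  cfg <- small_config(n_genotypes = 3)
  spec <- simulate_genotypes(cfg)
  for (g in seq_len(nrow(spec)))
    expect_true(all(diff(canopy_fraction(spec[g, ], 20:110)) >= 0))
})

test_that("with stay-green and greenness couplings off, yield is independent of post-flowering greenness", {
  cfg <- field_sim_config(n_genotypes = 25, pixels_per_plot = 800,
                          stay_green_gain = 0, greenness_yield_weight = 0,
                          staygreen_yield_weight = 0, seed = 5)
  season <- simulate_season(cfg)
  mb <- mean_bndvi_table(season$pixel_sets)
  late <- mb[mb$flight_day >= 79, ]
  post <- stats::aggregate(mean_bndvi ~ genotype_id, late, mean)
  gy <- stats::aggregate(yield_kg ~ genotype_id, season$traits, mean)
  df <- merge(post, gy, by = "genotype_id")
  r_obs <- cor(df$mean_bndvi, df$yield_kg)
  # permutation null at n = 25 genotypes
  set.seed(1)
  perm <- replicate(2000, cor(df$mean_bndvi, sample(df$yield_kg)))
  expect_gt(mean(abs(perm) >= abs(r_obs)), 0.01)
})

test_that("write_season round-trips pixel CSVs and the trait table", {
  cfg <- small_config(n_genotypes = 2, pixels_per_plot = 300)
  cfg$flight_days <- c(40L, 60L, 80L)
  cfg$flowering_window <- c(58L, 66L)
  season <- simulate_season(cfg)
  dir <- withr::local_tempdir()
  files <- write_season(season, dir, format = "csv")
  expect_length(files, length(season$pixel_sets) + 1)
  nm <- names(season$pixel_sets)[4]
  back <- read_pixel_csv(file.path(dir, paste0(nm, ".csv")))
  expect_equal(back$bndvi_values, season$pixel_sets[[nm]]$bndvi_values)
  traits_back <- read_trait_table(file.path(dir, "traits.csv"))
  expect_equal(traits_back$yield_kg, season$traits$yield_kg, tolerance = 1e-10)
})
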