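#' Per-plot-date mean canopy BNDVI table
#'
#' Applies [plot_mean_bndvi()] to every pixel set and returns a tidy table,
#' one row per plot-date. Plots with no canopy pixels get `NA` (with the
#' underlying warning suppressed, since early-season plots are expected).
#'
#' @param pixel_sets list of [plot_pixel_set()]s (e.g. `season$pixel_sets`).
#' @param threshold canopy/soil BNDVI cutoff (default 0.06).
#' @return data.frame: genotype_id, trial, flight_day, year, mean_bndvi.
#' @export
mean_bndvi_table <- function(pixel_sets, threshold = 0.06) {
  rows <- lapply(pixel_sets, function(ps) {
    data.frame(genotype_id = ps$genotype_id, trial = ps$trial,
               flight_day = ps$flight_day, year = ps$year,
               mean_bndvi = suppressWarnings(plot_mean_bndvi(ps, threshold)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the per-plot-date predictor table
#'
#' One row per plot-date observation with the predictors used in the
#' date-resolved correlation analyses: the retained component scores
#' (columns `PC1`, `PC2`, ...) and, optionally, mean canopy BNDVI.
#'
#' @param decomp a [fit_pca()] result.
#' @param components components to include (default 1:3).
#' @param mean_bndvi optional [mean_bndvi_table()] to merge in.
#' @return data.frame keyed by (genotype_id, trial, flight_day, year).
#' @export
predictor_table <- function(decomp, components = 1:3, mean_bndvi = NULL) {
  stopifnot(inherits(decomp, "histogram_decomposition"))
  df <- decomp$row_index
  for (comp in components) df[[paste0("PC", comp)]] <- decomp$scores[, comp]
  if (!is.null(mean_bndvi))
    df <- merge(df, mean_bndvi,
                by = c("genotype_id", "trial", "flight_day", "year"),
                all.x = TRUE, sort = FALSE)
  df
}

#' Date-resolved Pearson correlation of predictors with a trait
#'
#' For each year, flight date and predictor, computes the Pearson
#' correlation across plots (each genotype x trial an observation, matching
#' how plots are phenotyped; set `by_genotype_mean = TRUE` to first average
#' trials) between the predictor and the named trait, with a two-sided
#' p-value from the t distribution on n - 2 degrees of freedom and a
#' significance flag at p < 0.05. No multiple-testing correction is applied
#' by default, mirroring per-date significance marking; set `p_adjust` to
#' e.g. `"BH"` to correct across all dates/predictors of a trait.
#'
#' @param predictors a [predictor_table()] (any numeric columns beyond the
#'   keys are treated as predictors, or give `predictor_names`).
#' @param traits a [trait_table()].
#' @param trait_name one of tassel_day, silk_day, yield_kg, kernel_length,
#'   kernel_width, kernel_thickness.
#' @param predictor_names predictors to use (default: all non-key numeric
#'   columns).
#' @param by_genotype_mean average trials before correlating (default FALSE).
#' @param p_adjust method passed to [stats::p.adjust()] (default "none").
#' @param alpha significance level for the flag (default 0.05).
#' @return data.frame of class `correlation_series`: year, flight_day,
#'   predictor, trait, r, p, n, significant, reason (NA unless r is
#'   undefined).
#' @export
correlate_by_date <- function(predictors, traits, trait_name,
                              predictor_names = NULL,
                              by_genotype_mean = FALSE,
                              p_adjust = "none", alpha = 0.05) {
  stopifnot(trait_name %in% names(traits))
  keys <- c("genotype_id", "trial", "flight_day", "year")
  if (is.null(predictor_names)) {
    predictor_names <- setdiff(names(predictors)[vapply(predictors, is.numeric, TRUE)],
                               keys)
  }
  df <- merge(predictors, traits[, c("genotype_id", "trial", "year", trait_name)],
              by = c("genotype_id", "trial", "year"), sort = FALSE)
  if (by_genotype_mean) {
    form <- stats::as.formula(paste(
      "cbind(", paste(c(predictor_names, trait_name), collapse = ", "),
      ") ~ year + flight_day + genotype_id"))
    df <- stats::aggregate(form, df, mean)
  }
  out <- list()
  for (yr in unique(df$year)) for (day in sort(unique(df$flight_day[df$year == yr]))) {
    sub <- df[df$year == yr & df$flight_day == day, ]
    for (pn in predictor_names) {
      x <- sub[[pn]]; y <- sub[[trait_name]]
      ok <- stats::complete.cases(x, y)
      x <- x[ok]; y <- y[ok]
      n <- length(x)
      if (n < 3) {
        rec <- list(r = NA_real_, p = NA_real_, reason = "fewer than 3 plots")
      } else if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        rec <- list(r = NA_real_, p = NA_real_,
                    reason = "zero-variance predictor or trait")
      } else {
        ct <- stats::cor.test(x, y, method = "pearson")
        rec <- list(r = unname(ct$estimate), p = ct$p.value, reason = NA_character_)
      }
      out[[length(out) + 1L]] <- data.frame(
        year = yr, flight_day = day, predictor = pn, trait = trait_name,
        r = rec$r, p = rec$p, n = n, reason = rec$reason,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$p <- stats::p.adjust(res$p, method = p_adjust)
  res$significant <- !is.na(res$p) & res$p < alpha
  res <- res[, c("year", "flight_day", "predictor", "trait",
                 "r", "p", "n", "significant", "reason")]
  class(res) <- c("correlation_series", "data.frame")
  res
}

#' Compare low- vs high-yielding genotype groups over the season
#'
#' Ranks genotypes by trial-averaged grain yield within each year, takes the
#' `low_n` lowest- and `high_n` highest-yielding genotypes, and at each
#' flight date compares each predictor between the two groups (plots as
#' observations) with Welch's two-sample t-test, flagging p < 0.05.
#'
#' @inheritParams correlate_by_date
#' @param low_n,high_n group sizes (defaults 6 and 7).
#' @return data.frame: year, flight_day, predictor, mean_low, mean_high,
#'   p, significant.
#' @export
compare_yield_groups <- function(predictors, traits, low_n = 6L, high_n = 7L,
                                 predictor_names = NULL, alpha = 0.05) {
  keys <- c("genotype_id", "trial", "flight_day", "year")
  if (is.null(predictor_names))
    predictor_names <- setdiff(names(predictors)[vapply(predictors, is.numeric, TRUE)],
                               keys)
  out <- list()
  for (yr in unique(predictors$year)) {
    ty <- traits[traits$year == yr, ]
    gy <- tapply(ty$yield_kg, ty$genotype_id, mean)
    if (low_n + high_n > length(gy))
      stop(sprintf("compare_yield_groups: %d genotypes cannot form disjoint groups of %d and %d",
                   length(gy), low_n, high_n))
    ranked <- names(sort(gy))
    low <- ranked[seq_len(low_n)]
    high <- rev(ranked)[seq_len(high_n)]
    py <- predictors[predictors$year == yr, ]
    for (day in sort(unique(py$flight_day))) {
      sub <- py[py$flight_day == day, ]
      for (pn in predictor_names) {
        x <- sub[[pn]][sub$genotype_id %in% low]
        y <- sub[[pn]][sub$genotype_id %in% high]
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        p <- welch_p(x, y)
        out[[length(out) + 1L]] <- data.frame(
          year = yr, flight_day = day, predictor = pn,
          mean_low = mean(x), mean_high = mean(y), p = p,
          significant = !is.na(p) && p < alpha,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Welch t-test p-value, tolerating the degenerate equal-and-constant case
welch_p <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  stats::t.test(x, y)$p.value
}

#' Detect the pre-flowering dip in a mean-BNDVI time series
#'
#' Locates the deepest interior local minimum of the series within a
#' mid-season search window (between the canopy-closure rise and the
#' senescent decline), and reports its flight day and depth, measured as
#' the drop below the straight line joining the two flanking observations.
#' Returns "not found" when no interior local minimum exists in the window
#' or the deepest one is shallower than `min_depth`.
#'
#' @param days strictly increasing flight days (>= 5 required).
#' @param values mean canopy BNDVI at each day.
#' @param window absolute-day search window `c(lo, hi)` (default: the whole
#'   interior); season-level callers typically pass mean flowering day
#'   -15/+5.
#' @param min_depth minimum depth (BNDVI units) to count as a dip.
#' @return list with `found` (logical), `day`, `depth` (NA when not found).
#' @export
#' @examples
#' detect_flowering_dip(c(40, 50, 55, 60, 70), c(0.5, 0.8, 0.7, 0.85, 0.6))
#' # dip at day 55, depth 0.825 - 0.7 = 0.125
detect_flowering_dip <- function(days, values, window = NULL,
                                 min_depth = 0.01) {
  k <- length(days)
  if (k < 5 || length(values) != k)
    stop("detect_flowering_dip: need >= 5 (day, value) pairs")
  if (any(diff(days) <= 0)) stop("detect_flowering_dip: days must increase")
  if (is.null(window)) window <- range(days)
  best <- list(found = FALSE, day = NA_real_, depth = NA_real_)
  for (i in 2:(k - 1)) {
    if (days[i] < window[1] || days[i] > window[2]) next
    if (!(values[i] < values[i - 1] && values[i] <= values[i + 1])) next
    interp <- values[i - 1] + (values[i + 1] - values[i - 1]) *
      (days[i] - days[i - 1]) / (days[i + 1] - days[i - 1])
    depth <- interp - values[i]
    if (depth >= min_depth && (!best$found || depth > best$depth))
      best <- list(found = TRUE, day = days[i], depth = depth)
  }
  best
}

#' Dip detection across all genotypes of a season
#'
#' Trial-averages each genotype's mean canopy BNDVI series and runs
#' [detect_flowering_dip()] in a window around the per-year mean flowering
#' (tassel) day.
#'
#' @param mean_bndvi a [mean_bndvi_table()].
#' @param traits a [trait_table()] (supplies tassel days).
#' @param window_rel window relative to mean flowering day (default
#'   c(-15, 5)).
#' @param min_depth minimum dip depth (default 0.01).
#' @return data.frame: year, genotype_id, found, dip_day, depth.
#' @export
detect_season_dips <- function(mean_bndvi, traits, window_rel = c(-15, 5),
                               min_depth = 0.01) {
  agg <- stats::aggregate(mean_bndvi ~ year + genotype_id + flight_day,
                          mean_bndvi, mean, na.action = stats::na.omit)
  mean_flower <- tapply(traits$tassel_day, traits$year, mean)
  out <- list()
  for (yr in unique(agg$year)) for (g in unique(agg$genotype_id[agg$year == yr])) {
    sub <- agg[agg$year == yr & agg$genotype_id == g, ]
    sub <- sub[order(sub$flight_day), ]
    dip <- detect_flowering_dip(sub$flight_day, sub$mean_bndvi,
                                window = mean_flower[[yr]] + window_rel,
                                min_depth = min_depth)
    out[[length(out) + 1L]] <- data.frame(
      year = yr, genotype_id = g, found = dip$found,
      dip_day = dip$day, depth = dip$depth, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
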