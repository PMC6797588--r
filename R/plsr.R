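#' Configuration for PLS-R trait prediction
#'
#' @param n_draws number of repeated hold-out draws (default 100).
#' @param holdout_fraction fraction of plots held out per draw (default 0.30).
#' @param max_factors maximum number of latent factors fitted (default 15;
#'   capped at run time by rank and sample size).
#' @param feature_source `"pc_scores"` (per-date retained component scores)
#'   or `"raw_histograms"` (per-date 999-bin histograms).
#' @param grouped_split if `TRUE`, hold-out draws sample whole genotypes, so
#'   both trial replicates of a genotype land in the same partition. The
#'   default `FALSE` samples plots unrestrictedly; with replicated trials
#'   that lets the model recover a genotype's hold-out replicate from its
#'   training replicate, so unrestricted hold-out r partly measures
#'   genotype repeatability rather than pure out-of-genotype prediction.
#' @param seed master seed; each draw uses a deterministic sub-seed.
#' @return a validated list of class `plsr_config`.
#' @export
plsr_config <- function(n_draws = 100L, holdout_fraction = 0.30,
                        max_factors = 15L,
                        feature_source = c("pc_scores", "raw_histograms"),
                        grouped_split = FALSE,
                        seed = 1L) {
  feature_source <- match.arg(feature_source)
  if (holdout_fraction <= 0 || holdout_fraction >= 1)
    stop("plsr_config: holdout_fraction must be in (0, 1)")
  if (n_draws < 2) stop("plsr_config: n_draws must be >= 2")
  if (max_factors < 1) stop("plsr_config: max_factors must be >= 1")
  structure(list(n_draws = as.integer(n_draws),
                 holdout_fraction = holdout_fraction,
                 max_factors = as.integer(max_factors),
                 feature_source = feature_source,
                 grouped_split = isTRUE(grouped_split),
                 seed = as.integer(seed)),
            class = "plsr_config")
}

#' Assemble the per-plot season-profile feature matrix
#'
#' Builds one feature row per plot (genotype x trial) of a year by
#' concatenating, over flight dates in increasing order, either the plot's
#' retained component scores or its raw histogram bins. The row order and
#' the returned `plots` table align the features with the 2g rows of the
#' year's trait table. A plot missing a date has that date's block imputed
#' by the column mean over available plots (imputation count reported via
#' `message` and the `n_imputed` attribute); a date missing for every plot
#' is dropped with a warning.
#'
#' @param x a [fit_pca()] decomposition (for `source = "pc_scores"`) or a
#'   [stack_histograms()] matrix (for `source = "raw_histograms"`).
#' @param year year label to extract.
#' @param source `"pc_scores"` or `"raw_histograms"`.
#' @return list of class `plsr_features`: `features` (plots x (dates *
#'   block)), `plots` (genotype_id, trial, year per row), `flight_days`.
#' @export
assemble_feature_matrix <- function(x, year,
                                    source = c("pc_scores", "raw_histograms")) {
  source <- match.arg(source)
  if (source == "pc_scores") {
    stopifnot(inherits(x, "histogram_decomposition"))
    V <- x$scores
    ri <- x$row_index
    block_names <- paste0("PC", seq_len(ncol(V)))
  } else {
    V <- x$X
    ri <- x$row_index
    block_names <- sprintf("b%04d", seq_len(ncol(V)))
  }
  keep <- ri$year == year
  if (!any(keep)) stop("assemble_feature_matrix: no rows for year ", year)
  V <- V[keep, , drop = FALSE]
  ri <- ri[keep, , drop = FALSE]
  days <- sort(unique(ri$flight_day))
  plots <- unique(ri[, c("genotype_id", "trial")])
  plots <- plots[order(plots$genotype_id, plots$trial), , drop = FALSE]
  plots$year <- year
  rownames(plots) <- NULL
  q <- ncol(V)
  feat <- matrix(NA_real_, nrow(plots), q * length(days))
  colnames(feat) <- paste0(rep(sprintf("d%03d", days), each = q), "_",
                           rep(block_names, length(days)))
  key_obs <- paste(ri$genotype_id, ri$trial)
  key_plot <- paste(plots$genotype_id, plots$trial)
  for (j in seq_along(days)) {
    sel <- ri$flight_day == days[j]
    rows <- match(key_obs[sel], key_plot)
    feat[rows, (j - 1) * q + seq_len(q)] <- V[sel, , drop = FALSE]
  }
  all_missing <- apply(feat, 2, function(col) all(is.na(col)))
  if (any(all_missing)) {
    warning("assemble_feature_matrix: dropping date block(s) with no data: ",
            paste(unique(sub("_.*", "", colnames(feat)[all_missing])),
                  collapse = ", "))
    feat <- feat[, !all_missing, drop = FALSE]
  }
  n_imputed <- sum(is.na(feat))
  if (n_imputed > 0) {
    message(sprintf("assemble_feature_matrix: imputing %d missing cell(s) by column means",
                    n_imputed))
    for (j in which(colSums(is.na(feat)) > 0))
      feat[is.na(feat[, j]), j] <- mean(feat[, j], na.rm = TRUE)
  }
  structure(list(features = feat, plots = plots, flight_days = days,
                 source = source, n_imputed = n_imputed),
            class = "plsr_features")
}

#' Fit a univariate-response PLS regression (NIPALS)
#'
#' Mean-centres X and y, then extracts latent factors by the NIPALS
#' recursion: the factor weight is the normalised covariance direction
#' X'y / ||X'y||, the factor score is X projected on it, X is deflated by
#' the score's loading and y by its regression on the score. Regression
#' coefficient vectors are assembled for every factor count 1..n_factors so
#' predictions can be evaluated along the whole factor path.
#'
#' @param X feature matrix (n x p), or a `plsr_features` object.
#' @param y numeric response, length n.
#' @param n_factors number of factors to extract (truncated with a warning
#'   if it exceeds the data rank).
#' @return an object of class `plsr_model`: `n_factors`, `x_mean`,
#'   `y_mean`, `weights` (p x A), `loadings` (p x A), `q` (per-factor y
#'   regressions), `scores` (n x A), `coef_path` (p x A; column a gives the
#'   coefficients of the a-factor model), `coefficients` (= last column).
#' @export
fit_plsr <- function(X, y, n_factors) {
  if (inherits(X, "plsr_features")) X <- X$features
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), nrow(X) >= 2)
  if (stats::sd(y) == 0) stop("fit_plsr: zero-variance response")
  if (n_factors > min(nrow(X) - 1, ncol(X)))
    stop("fit_plsr: n_factors exceeds min(rows - 1, features)")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)
  f <- y - y_mean
  p <- ncol(X)
  W <- P <- matrix(0, p, n_factors)
  Tm <- matrix(0, nrow(X), n_factors)
  q <- numeric(n_factors)
  A <- n_factors
  tol <- 1e-12 * max(1, sum(E^2))
  for (a in seq_len(n_factors)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw^2 <= tol) {
      warning(sprintf("fit_plsr: data rank exhausted at %d factor(s); truncating", a - 1L))
      A <- a - 1L
      break
    }
    w <- w / nw
    t_a <- E %*% w
    tt <- sum(t_a^2)
    if (tt <= tol) {
      warning(sprintf("fit_plsr: degenerate factor score at factor %d; truncating", a))
      A <- a - 1L
      break
    }
    p_a <- crossprod(E, t_a) / tt
    q[a] <- sum(f * t_a) / tt
    E <- E - t_a %*% t(p_a)
    f <- f - q[a] * t_a
    W[, a] <- w
    P[, a] <- p_a
    Tm[, a] <- t_a
  }
  if (A == 0) stop("fit_plsr: no usable factor (X has no covariance with y)")
  W <- W[, seq_len(A), drop = FALSE]
  P <- P[, seq_len(A), drop = FALSE]
  Tm <- Tm[, seq_len(A), drop = FALSE]
  q <- q[seq_len(A)]
  coef_path <- matrix(0, p, A)
  for (a in seq_len(A)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    coef_path[, a] <- Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)])
  }
  structure(list(n_factors = A, x_mean = x_mean, y_mean = y_mean,
                 weights = W, loadings = P, q = q, scores = Tm,
                 coef_path = coef_path,
                 coefficients = coef_path[, A]),
            class = "plsr_model")
}

#' Predict from a fitted PLS model
#'
#' @param object a [fit_plsr()] model.
#' @param newdata feature matrix (n x p) or `plsr_features`.
#' @param n_factors factor count to predict with (default: all fitted;
#'   0 returns the training response mean).
#' @param ... ignored.
#' @return numeric predictions.
#' @export
predict.plsr_model <- function(object, newdata, n_factors = object$n_factors,
                               ...) {
  if (inherits(newdata, "plsr_features")) newdata <- newdata$features
  newdata <- as.matrix(newdata)
  stopifnot(n_factors >= 0, n_factors <= object$n_factors)
  if (n_factors == 0) return(rep(object$y_mean, nrow(newdata)))
  drop(object$y_mean +
         sweep(newdata, 2, object$x_mean) %*% object$coef_path[, n_factors])
}

#' Repeated hold-out evaluation of PLS along the factor path
#'
#' For each of `n_draws` deterministic sub-seeded draws, holds out a random
#' `holdout_fraction` of the plots, fits PLS on the remainder, and records
#' the Pearson correlation between predicted and observed response on the
#' hold-out set at every factor count 1..max_factors. A draw whose hold-out
#' (or training) response is constant is re-sampled and the event counted.
#'
#' @param X feature matrix or `plsr_features` (the latter also supplies
#'   genotype ids for grouped splits).
#' @param y numeric response aligned to the rows of `X`.
#' @param config a [plsr_config()].
#' @param groups optional grouping labels (e.g. genotype ids) used when
#'   `config$grouped_split` is `TRUE`; defaults to the `plots` table of a
#'   `plsr_features` input.
#' @return list of class `plsr_holdout`: `r_curves` (n_draws x A matrix),
#'   `n_factors` (A actually evaluated), `n_resampled`.
#' @export
holdout_evaluate <- function(X, y, config, groups = NULL) {
  stopifnot(inherits(config, "plsr_config"))
  if (inherits(X, "plsr_features")) {
    if (is.null(groups)) groups <- X$plots$genotype_id
    X <- X$features
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  n_hold <- round(config$holdout_fraction * n)
  if (n_hold < 3 || n - n_hold < 3)
    stop("holdout_evaluate: both partitions need >= 3 plots")
  if (config$grouped_split && is.null(groups))
    stop("holdout_evaluate: grouped_split requires group labels")
  A <- min(config$max_factors, n - n_hold - 1, ncol(X))
  r_curves <- matrix(NA_real_, config$n_draws, A)
  n_resampled <- 0L
  draw_split <- function(s) {
    if (config$grouped_split) {
      g <- unique(groups)
      n_hold_g <- max(1, round(config$holdout_fraction * length(g)))
      which(groups %in% with_seed(s, sample(g, n_hold_g)))
    } else {
      with_seed(s, sample.int(n, n_hold))
    }
  }
  for (d in seq_len(config$n_draws)) {
    for (attempt in 1:100) {
      hold <- draw_split(sub_seed(config$seed, "holdout", d, attempt))
      if (length(hold) >= 3 && n - length(hold) >= 3 &&
          stats::sd(y[hold]) > 0 && stats::sd(y[-hold]) > 0) break
      n_resampled <- n_resampled + 1L
      if (attempt == 100) stop("holdout_evaluate: cannot draw a non-degenerate split")
    }
    fit <- fit_plsr(X[-hold, , drop = FALSE], y[-hold],
                    min(A, n - length(hold) - 1))
    for (a in seq_len(A)) {
      pred <- if (a <= fit$n_factors)
        predict(fit, X[hold, , drop = FALSE], n_factors = a)
      else predict(fit, X[hold, , drop = FALSE], n_factors = fit$n_factors)
      r_curves[d, a] <- if (stats::sd(pred) == 0) 0
        else stats::cor(pred, y[hold])
    }
  }
  structure(list(r_curves = r_curves, n_factors = A,
                 n_resampled = n_resampled),
            class = "plsr_holdout")
}

#' Factor threshold of a hold-out performance curve
#'
#' The factor count at which predictive power begins to diminish: the
#' smallest k with r(k) >= r(k+1) (the curve's first local maximum), or the
#' last factor count if the curve increases throughout. A flat stretch
#' counts as diminishing, so a constant curve yields 1. The alternative
#' `"one_se"` rule returns the smallest k whose r is within one standard
#' error (over the curve's values) of the maximum.
#'
#' @param curve numeric vector of hold-out r at factor counts 1, 2, ...
#' @param rule `"first_local_max"` (default) or `"one_se"`.
#' @return integer factor threshold in [1, length(curve)].
#' @export
#' @examples
#' select_factor_threshold(c(0.3, 0.5, 0.6, 0.55, 0.4))  # 3
select_factor_threshold <- function(curve,
                                    rule = c("first_local_max", "one_se")) {
  rule <- match.arg(rule)
  stopifnot(length(curve) >= 2, all(is.finite(curve)))
  if (rule == "one_se") {
    se <- stats::sd(curve) / sqrt(length(curve))
    return(which(curve >= max(curve) - se)[1])
  }
  for (k in seq_len(length(curve) - 1))
    if (curve[k] >= curve[k + 1]) return(k)
  length(curve)
}

#' PLS-R trait prediction report
#'
#' For each requested trait: runs [holdout_evaluate()], finds each draw's
#' factor threshold f_T and its hold-out correlation at f_T, and reports
#' the mean hold-out r over draws together with the average factor
#' threshold f_A. Traits are aligned to the feature rows through the
#' `plots` table of the feature object.
#'
#' @param features a [assemble_feature_matrix()] result.
#' @param traits a [trait_table()] for the same year.
#' @param config a [plsr_config()].
#' @param trait_names traits to predict (default: all six).
#' @param threshold_rule passed to [select_factor_threshold()].
#' @return data.frame of class `plsr_report` (trait, year, mean_holdout_r,
#'   f_A, n_draws, n_factors_evaluated), with the per-draw table in
#'   `attr(, "per_draw")` and the full r curves in `attr(, "r_curves")`.
#' @export
predict_traits_report <- function(features, traits, config,
                                  trait_names = c("tassel_day", "silk_day",
                                                  "yield_kg", "kernel_length",
                                                  "kernel_width",
                                                  "kernel_thickness"),
                                  threshold_rule = "first_local_max") {
  stopifnot(inherits(features, "plsr_features"),
            inherits(config, "plsr_config"))
  yr <- features$plots$year[1]
  ty <- traits[traits$year == yr, , drop = FALSE]
  ord <- match(paste(features$plots$genotype_id, features$plots$trial),
               paste(ty$genotype_id, ty$trial))
  if (anyNA(ord))
    stop("predict_traits_report: trait rows missing for some plots")
  ty <- ty[ord, , drop = FALSE]
  rows <- list()
  per_draw <- list()
  curves <- list()
  for (tr in trait_names) {
    he <- holdout_evaluate(features, ty[[tr]], config,
                           groups = features$plots$genotype_id)
    f_t <- apply(he$r_curves, 1, select_factor_threshold,
                 rule = threshold_rule)
    r_at <- he$r_curves[cbind(seq_len(nrow(he$r_curves)), f_t)]
    rows[[tr]] <- data.frame(trait = tr, year = yr,
                             mean_holdout_r = mean(r_at),
                             f_A = mean(f_t), n_draws = config$n_draws,
                             n_factors_evaluated = he$n_factors,
                             stringsAsFactors = FALSE)
    per_draw[[tr]] <- data.frame(trait = tr, draw = seq_along(f_t),
                                 f_T = f_t, r_at_fT = r_at,
                                 stringsAsFactors = FALSE)
    curves[[tr]] <- he$r_curves
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_draw") <- do.call(rbind, per_draw)
  attr(out, "r_curves") <- curves
  class(out) <- c("plsr_report", "data.frame")
  out
}

#' Compare hold-out r distributions from two feature sources
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test between the per-draw
#' hold-out correlations of two reports (e.g. PC-score features vs raw
#' histograms) for each trait common to both.
#'
#' @param report_a,report_b [predict_traits_report()] results.
#' @param alpha significance level (default 0.05).
#' @return data.frame: trait, mean_r_a, mean_r_b, p, different (flag at
#'   `alpha`).
#' @export
compare_feature_sources <- function(report_a, report_b, alpha = 0.05) {
  da <- attr(report_a, "per_draw")
  db <- attr(report_b, "per_draw")
  out <- list()
  for (tr in intersect(unique(da$trait), unique(db$trait))) {
    ra <- da$r_at_fT[da$trait == tr]
    rb <- db$r_at_fT[db$trait == tr]
    p <- if (isTRUE(all.equal(sort(ra), sort(rb)))) 1
      else suppressWarnings(stats::wilcox.test(ra, rb)$p.value)
    out[[tr]] <- data.frame(trait = tr, mean_r_a = mean(ra),
                            mean_r_b = mean(rb), p = p,
                            different = p < alpha,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
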