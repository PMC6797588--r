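test_that("the first PLS weight is the normalised covariance direction X'y", {
  set.seed(41)
  X <- matrix(rnorm(30 * 7), 30, 7)
  y <- rnorm(30)
  fit <- fit_plsr(X, y, n_factors = 3)
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  w1 <- crossprod(Xc, yc)
  w1 <- w1 / sqrt(sum(w1^2))
  expect_equal(fit$weights[, 1], as.numeric(w1), tolerance = 1e-10)
})

test_that("full-factor PLS reproduces the least-squares fit in sample", {
  set.seed(43)
  X <- matrix(rnorm(25 * 6), 25, 6)
  y <- drop(X %*% rnorm(6)) + rnorm(25)
  fit <- fit_plsr(X, y, n_factors = 6)
  ols <- lm.fit(cbind(1, X), y)
  expect_equal(predict(fit, X), unname(ols$fitted.values), tolerance = 1e-6)
})

test_that("factor scores are mutually orthogonal and zero factors predict the mean", {
  set.seed(47)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- rnorm(40)
  fit <- fit_plsr(X, y, n_factors = 5)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8 * max(diag(G)))
  expect_equal(predict(fit, X[1:3, ], n_factors = 0), rep(mean(y), 3))
})

test_that("prediction is centred correctly and equivariant under y scaling", {
  set.seed(53)
  X <- matrix(rnorm(30 * 5), 30, 5)
  y <- drop(X %*% c(1, -2, 0, 0.5, 0)) + rnorm(30, sd = 0.2)
  new <- matrix(rnorm(10 * 5), 10, 5)
  p0 <- predict(fit_plsr(X, y, 3), new, 3)
  expect_equal(predict(fit_plsr(X, y + 100, 3), new, 3), p0 + 100,
               tolerance = 1e-8)
  expect_equal(predict(fit_plsr(X, 2.5 * y, 3), new, 3), 2.5 * p0,
               tolerance = 1e-8)
})

test_that("degenerate responses and excess factors are rejected", {
  X <- matrix(rnorm(20 * 4), 20, 4)
  expect_error(fit_plsr(X, rep(1, 20), 2), "zero-variance")
  expect_error(fit_plsr(X, rnorm(20), 5), "exceeds")
  # exact low-rank X truncates with a warning
  Xlr <- cbind(X[, 1], X[, 1], X[, 1], X[, 1])
  expect_warning(fit <- fit_plsr(Xlr, drop(X[, 1]) + rnorm(20, sd = 1e-8), 3),
                 "truncating")
  expect_lt(fit$n_factors, 3)
})

test_that("noise-free linear signals are recovered exactly on hold-out data", {
  set.seed(59)
  # single informative feature: one factor is simple regression, r = 1
  X1 <- matrix(rnorm(30), 30, 1)
  he1 <- holdout_evaluate(X1, 2 * X1[, 1], plsr_config(n_draws = 5, seed = 3,
                                                       max_factors = 1))
  expect_equal(he1$r_curves[, 1], rep(1, 5), tolerance = 1e-8)
  # multi-feature: the full-factor model equals OLS, which is exact here
  X <- matrix(rnorm(30 * 4), 30, 4)
  he <- holdout_evaluate(X, 2 * X[, 3], plsr_config(n_draws = 5, seed = 3,
                                                    max_factors = 4))
  expect_equal(he$r_curves[, 4], rep(1, 5), tolerance = 1e-8)
})

test_that("hold-out curves are deterministic under a fixed seed", {
  set.seed(61)
  X <- matrix(rnorm(40 * 8), 40, 8)
  y <- drop(X %*% rnorm(8)) + rnorm(40)
  cfg <- plsr_config(n_draws = 8, seed = 77, max_factors = 5)
  expect_identical(holdout_evaluate(X, y, cfg)$r_curves,
                   holdout_evaluate(X, y, cfg)$r_curves)
})

test_that("factor threshold selection follows the first-local-maximum rule", {
  expect_equal(select_factor_threshold(c(0.3, 0.5, 0.6, 0.55, 0.4)), 3)
  expect_equal(select_factor_threshold(c(0.1, 0.2, 0.3)), 3)   # increasing
  expect_equal(select_factor_threshold(c(0.4, 0.4, 0.4)), 1)   # flat tie
  expect_equal(select_factor_threshold(c(0.5, 0.3, 0.8)), 1)
  one_se <- select_factor_threshold(c(0.3, 0.59, 0.6, 0.55, 0.4),
                                    rule = "one_se")
  expect_lte(one_se, 3)
})

test_that("feature assembly has the documented dimensions and row alignment", {
  n_g <- 10; dates <- seq(40, 89, by = 7); k <- 15
  ri <- expand.grid(trial = 1:2, genotype_id = sprintf("G%02d", 1:n_g),
                    flight_day = dates, stringsAsFactors = FALSE)
  ri$year <- "Y1"
  set.seed(67)
  scores <- matrix(rnorm(nrow(ri) * k), nrow(ri), k)
  d <- toy_decomposition(scores, ri, m = k)
  feats <- assemble_feature_matrix(d, "Y1", "pc_scores")
  expect_equal(dim(feats$features), c(20, 8 * 15))
  expect_equal(nrow(feats$plots), 20)
  # each block of a plot's row equals that plot-date's score vector
  i <- which(ri$genotype_id == "G03" & ri$trial == 2 & ri$flight_day == dates[4])
  row <- which(feats$plots$genotype_id == "G03" & feats$plots$trial == 2)
  expect_equal(feats$features[row, (3 * k + 1):(4 * k)],
               scores[i, ], ignore_attr = TRUE)
  # raw-histogram source dimensions
  hm <- list(X = matrix(runif(nrow(ri) * 20), nrow(ri), 20), row_index = ri)
  fh <- assemble_feature_matrix(hm, "Y1", "raw_histograms")
  expect_equal(dim(fh$features), c(20, 8 * 20))
  # a missing plot-date block is mean-imputed
  keep <- !(ri$genotype_id == "G01" & ri$trial == 1 & ri$flight_day == dates[1])
  d2 <- toy_decomposition(scores[keep, ], ri[keep, ], m = k)
  expect_message(f2 <- assemble_feature_matrix(d2, "Y1", "pc_scores"),
                 "imputing")
  expect_equal(f2$n_imputed, k)
  r1 <- which(f2$plots$genotype_id == "G01" & f2$plots$trial == 1)
  expect_equal(f2$features[r1, 1:k],
               colMeans(f2$features[-r1, 1:k]), ignore_attr = TRUE)
})

test_that("trait report aligns rows, averages per-draw thresholds, and compares sources", {
  set.seed(71)
  n_g <- 12; dates <- c(40, 50, 60); k <- 4
  ri <- expand.grid(trial = 1:2, genotype_id = sprintf("G%02d", 1:n_g),
                    flight_day = dates, stringsAsFactors = FALSE)
  ri$year <- "Y1"
  scores <- matrix(rnorm(nrow(ri) * k), nrow(ri), k)
  d <- toy_decomposition(scores, ri, m = k)
  feats <- assemble_feature_matrix(d, "Y1", "pc_scores")
  # yield is a clean linear readout of the features; tassel is pure noise
  beta <- rnorm(ncol(feats$features))
  yield <- drop(feats$features %*% beta)
  yield <- 15 + 3 * yield / sd(yield)
  traits <- toy_traits(feats$plots$genotype_id, trial = feats$plots$trial,
                       tassel_day = rnorm(24, 60, 2), yield_kg = yield)
  # shuffle trait rows: alignment must be restored internally
  traits <- traits[sample(nrow(traits)), ]
  cfg <- plsr_config(n_draws = 20, seed = 5, max_factors = 6)
  rep1 <- predict_traits_report(feats, traits, cfg,
                                trait_names = c("tassel_day", "yield_kg"))
  expect_equal(rep1$trait, c("tassel_day", "yield_kg"))
  expect_gt(rep1$mean_holdout_r[rep1$trait == "yield_kg"], 0.9)
  expect_lt(abs(rep1$mean_holdout_r[rep1$trait == "tassel_day"]), 0.45)
  pd <- attr(rep1, "per_draw")
  expect_true(all(pd$f_T >= 1 & pd$f_T <= 6))
  expect_equal(rep1$f_A[1], mean(pd$f_T[pd$trait == "tassel_day"]))
  # identical feature sources -> comparison flags nothing, p in the 1 class
  cmp <- compare_feature_sources(rep1, rep1)
  expect_true(all(cmp$p == 1))
  expect_false(any(cmp$different))
})

test_that("grouped splits remove replicate leakage for genotype-level noise traits", {
  # a trait that is pure genotype-level noise (no canopy coupling) can be
  # "predicted" under unrestricted hold-out by recovering a genotype's
  # held-out replicate from its training replicate; sampling whole
  # genotypes removes that route
  set.seed(73)
  n_g <- 15; dates <- seq(40, 75, by = 5); k <- 6
  ri <- expand.grid(trial = 1:2, genotype_id = sprintf("G%02d", 1:n_g),
                    flight_day = dates, stringsAsFactors = FALSE)
  ri$year <- "Y1"
  geno_sig <- matrix(rnorm(n_g * k), n_g, k)  # genotype-specific signatures
  scores <- geno_sig[match(ri$genotype_id, sprintf("G%02d", 1:n_g)), ] +
    matrix(rnorm(nrow(ri) * k, sd = 0.1), nrow(ri), k)
  d <- toy_decomposition(scores, ri, m = k)
  feats <- assemble_feature_matrix(d, "Y1", "pc_scores")
  trait_g <- rnorm(n_g)
  y <- trait_g[match(feats$plots$genotype_id, sprintf("G%02d", 1:n_g))]
  he_free <- holdout_evaluate(feats, y, plsr_config(n_draws = 15, seed = 9,
                                                    max_factors = 8))
  he_grp <- holdout_evaluate(feats, y,
                             plsr_config(n_draws = 15, seed = 9,
                                         max_factors = 8,
                                         grouped_split = TRUE))
  # compare mean hold-out r at fixed mid-path factor counts (a max over
  # factors would be selection-biased upward at these hold-out sizes)
  r_free <- mean(he_free$r_curves[, 2:6])
  r_grp <- mean(he_grp$r_curves[, 2:6])
  expect_gt(r_free, 0.35)          # leakage route exists
  expect_lt(r_grp, r_free - 0.25)  # and grouping closes most of it
})

test_that("count normalization preserves raw counts in the histogram slot", {
  v <- c(0.25, 0.25, 0.75)
  h <- build_histogram(v, n_bins = 4, normalize = "count")
  expect_equal(h$frequencies, c(2, 0, 1, 0))
  expect_equal(build_histogram(v, n_bins = 4)$frequencies,
               c(2, 0, 1, 0) / 3)
})
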