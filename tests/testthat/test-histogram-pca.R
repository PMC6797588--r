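toy_matrix <- function(n = 6, m = 4, seed = 99) {
  set.seed(seed)
  X <- matrix(runif(n * m), n, m)
  X <- X / rowSums(X)
  list(X = X, row_index = data.frame(genotype_id = paste0("G", seq_len(n)),
                                     trial = 1L, flight_day = 50,
                                     year = "Y1"))
}

test_that("SVD decomposition matches a brute-force covariance eigendecomposition", {
  tm <- toy_matrix()
  d <- fit_pca(tm, k_retained = 4)
  eig <- eigen(cov(tm$X), symmetric = TRUE)
  k <- d$k_retained
  expect_equal(d$eigenvalues, eig$values[seq_len(k)], tolerance = 1e-8)
  for (j in seq_len(k)) {
    # vectors agree up to sign
    expect_equal(abs(sum(d$eigenvectors[j, ] * eig$vectors[, j])), 1,
                 tolerance = 1e-8)
  }
  # orthonormal rows
  G <- d$eigenvectors %*% t(d$eigenvectors)
  expect_equal(G, diag(k), tolerance = 1e-8)
  # eigenvalues non-increasing, variance fractions sum to 1 over all comps
  expect_true(all(diff(d$eigenvalues) <= 1e-12))
  expect_equal(sum(d$variance_explained_all), 1, tolerance = 1e-12)
})

test_that("identical rows are a degenerate-input error", {
  X <- matrix(rep(c(0.2, 0.3, 0.5), each = 5), 5, 3)
  expect_error(fit_pca(list(X = X, row_index = NULL)), "identical")
  expect_error(fit_pca(list(X = X[1, , drop = FALSE], row_index = NULL)),
               "2 rows")
})

test_that("a rank-2 construction is explained >99% by two components", {
  set.seed(4)
  base <- rep(1 / 60, 60)
  f1 <- sin(seq(0, pi, length.out = 60)) / 30
  f2 <- cos(seq(0, 2 * pi, length.out = 60)) / 40
  X <- t(sapply(runif(30, -1, 1), function(a)
    base + a * f1 + runif(1, -1, 1) * f2 + rnorm(60, 0, 1e-6)))
  d <- fit_pca(list(X = X, row_index = NULL), k_retained = 5)
  expect_gt(sum(d$variance_explained[1:2]), 0.99)
})

test_that("projection identities hold and match an explicit dot-product loop", {
  an <- small_analysis()
  d <- an$decomp
  m <- length(d$mean_histogram)
  expect_equal(as.numeric(project(d, d$mean_histogram)),
               rep(0, d$k_retained), tolerance = 1e-12)
  c0 <- 0.37
  h <- d$mean_histogram + c0 * d$eigenvectors[3, ]
  sc <- as.numeric(project(d, h))
  expect_equal(sc[3], c0, tolerance = 1e-10)
  expect_equal(sc[-3], rep(0, d$k_retained - 1), tolerance = 1e-10)
  # loop oracle on a random histogram
  set.seed(8)
  hr <- runif(m); hr <- hr / sum(hr)
  sc <- as.numeric(project(d, hr))
  oracle <- numeric(d$k_retained)
  for (j in seq_len(d$k_retained)) {
    acc <- 0
    for (b in seq_len(m)) acc <- acc + (hr[b] - d$mean_histogram[b]) * d$eigenvectors[j, b]
    oracle[j] <- acc
  }
  expect_equal(sc, oracle, tolerance = 1e-12)
  # projecting the training rows reproduces the stored scores
  expect_equal(project(d, an$hm$X), d$scores, tolerance = 1e-10)
  expect_error(project(d, runif(10)), "does not match")
})

test_that("retaining all components reconstructs X", {
  tm <- toy_matrix(n = 8, m = 5, seed = 13)
  d <- fit_pca(tm, k_retained = 5)
  recon <- d$scores %*% d$eigenvectors +
    rep(d$mean_histogram, each = nrow(tm$X))
  expect_equal(recon, tm$X, tolerance = 1e-8)
})

test_that("sign convention makes the decomposition deterministic", {
  tm <- toy_matrix(n = 10, m = 6, seed = 2)
  d1 <- fit_pca(tm, k_retained = 4)
  d2 <- fit_pca(tm, k_retained = 4)
  expect_identical(d1$eigenvectors, d2$eigenvectors)
  expect_identical(d1$scores, d2$scores)
  # component 1 loads non-negatively on the sub-threshold (soil) bins
  an <- small_analysis()
  centers <- bin_centers(length(an$decomp$mean_histogram))
  expect_gte(sum(an$decomp$eigenvectors[1, centers < 0.06]), 0)
  # component 2 is oriented toward greater BNDVI
  expect_gte(sum(an$decomp$eigenvectors[2, ] * centers), 0)
})

test_that("back-projection sweep spans the observed score range and re-projects to itself", {
  an <- small_analysis()
  d <- an$decomp
  sw <- back_project_sweep(d, pc_index = 2, n_steps = 5)
  expect_equal(sw$sweep_scores[1], min(d$scores[, 2]))
  expect_equal(sw$sweep_scores[5], max(d$scores[, 2]))
  expect_true(all(diff(sw$sweep_scores) > 0))
  expect_equal(dim(sw$model_histograms), c(5, length(d$mean_histogram)))
  back <- project(d, sw$model_histograms)
  expect_equal(back[, 2], sw$sweep_scores, tolerance = 1e-10)
  expect_equal(max(abs(back[, -2])), 0, tolerance = 1e-10)
  # a zero score back-projects to the mean histogram
  mid <- back_project_sweep(d, 1, n_steps = 3)
  zero_model <- d$mean_histogram + 0 * d$eigenvectors[1, ]
  expect_equal(zero_model, d$mean_histogram)
  expect_error(back_project_sweep(d, d$k_retained + 1), "pc_index")
})

test_that("score time series aligns days to mean flowering and averages trials", {
  ri <- data.frame(genotype_id = "G1", trial = c(1L, 2L, 1L, 2L, 1L, 2L),
                   flight_day = rep(c(50, 60, 70), each = 2), year = "Y1")
  scores <- cbind(PC1 = c(1, 3, 2, 2, 5, 1), PC2 = 0, PC3 = 0, PC4 = 0)
  d <- toy_decomposition(scores, ri)
  traits <- toy_traits("G1", trial = 1:2, tassel_day = 60)
  ts <- score_time_series(d, traits, components = 1)
  expect_equal(ts$relative_day, c(-10, 0, 10))
  expect_equal(ts$score, c(2, 2, 3))
  expect_error(score_time_series(d, toy_traits("G1", year = "Y9")), "missing")
})

test_that("PC1 declines steeply early in the season on synthetic data", {
  an <- small_analysis()
  ts <- score_time_series(an$decomp, an$season$traits, components = 1)
  curve <- tapply(ts$score, ts$flight_day, mean)
  # early-season drop dominates: first-interval decrease is the largest
  expect_lt(curve[[2]] - curve[[1]], 0)
  expect_lt(curve[[3]] - curve[[2]], 0)
  expect_equal(which.min(diff(unname(curve))) <= 3, TRUE)
})

test_that("decomposition CSV serialization is faithful", {
  tm <- toy_matrix(n = 7, m = 5, seed = 31)
  d <- fit_pca(tm, k_retained = 3)
  prefix <- file.path(withr::local_tempdir(), "pca")
  write_decomposition(d, prefix)
  vec <- read.csv(paste0(prefix, "_eigenvectors.csv"), colClasses = "numeric")
  expect_identical(unname(as.matrix(vec)), unname(d$eigenvectors))
})
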