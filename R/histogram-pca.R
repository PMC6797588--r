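#' Principal component decomposition of the histogram matrix
#'
#' Column-mean centres X and computes its singular value decomposition; the
#' right singular vectors are the eigenvectors of the covariance matrix of
#' X and the principal axes of histogram-shape variation. Eigenvalues are
#' singular values squared over (n - 1); variance explained is each
#' eigenvalue over the total variance.
#'
#' SVD signs are arbitrary, so a fixed orientation makes the decomposition
#' deterministic and gives the components their field meaning: component 1
#' is oriented so its loadings over the sub-0.06 (soil) bins sum to a
#' non-negative value (higher score = more exposed soil, less canopy
#' closure); component 2 so that the loading-weighted bin position
#' `sum(loading * bin_center)` is non-negative (higher score = distribution
#' shifted toward greater BNDVI, i.e. a greener canopy); every further
#' component so its largest-magnitude loading is positive.
#'
#' @param hm a [stack_histograms()] result (or any list with matrix `X` and
#'   data.frame `row_index`).
#' @param k_retained number of components kept (default 15).
#' @param soil_threshold BNDVI value bounding the soil bins used by the
#'   component-1 sign rule (default 0.06).
#' @return an object of class `histogram_decomposition`: `mean_histogram`,
#'   `eigenvectors` (k x m, orthonormal rows), `eigenvalues` (k,
#'   non-increasing), `variance_explained` (k fractions of total variance),
#'   `variance_explained_all`, `scores` (n x k), `k_retained`, `row_index`.
#' @export
fit_pca <- function(hm, k_retained = 15L, soil_threshold = 0.06) {
  X <- hm$X
  stopifnot(is.matrix(X))
  n <- nrow(X); m <- ncol(X)
  if (k_retained < 1) stop("fit_pca: k_retained must be >= 1")
  if (n < 2) stop("fit_pca: need at least 2 rows")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (sum(Xc^2) < 1e-24)
    stop("fit_pca: degenerate input — all histogram rows are identical")
  sv <- svd(Xc)
  d2 <- sv$d^2
  k <- min(k_retained, sum(sv$d > max(sv$d) * 1e-12))
  V <- t(sv$v[, seq_len(k), drop = FALSE])       # k x m, rows orthonormal
  scores <- sv$u[, seq_len(k), drop = FALSE] *
    rep(sv$d[seq_len(k)], each = n)

  centers <- bin_centers(m)
  for (j in seq_len(k)) {
    flip <- if (j == 1) {
      sum(V[1, centers < soil_threshold]) < 0
    } else if (j == 2) {
      sum(V[2, ] * centers) < 0
    } else {
      V[j, which.max(abs(V[j, ]))] < 0
    }
    if (flip) {
      V[j, ] <- -V[j, ]
      scores[, j] <- -scores[, j]
    }
  }

  structure(list(mean_histogram = mu,
                 eigenvectors = V,
                 eigenvalues = d2[seq_len(k)] / (n - 1),
                 variance_explained = d2[seq_len(k)] / sum(d2),
                 variance_explained_all = d2 / sum(d2),
                 scores = scores,
                 k_retained = k,
                 row_index = hm$row_index),
            class = "histogram_decomposition")
}

#' @export
print.histogram_decomposition <- function(x, ...) {
  ve <- x$variance_explained
  cat(sprintf("<histogram_decomposition> %d components retained over %d bins; variance explained: %s (cum %.1f%%)\n",
              x$k_retained, length(x$mean_histogram),
              paste(sprintf("%.1f%%", 100 * ve[seq_len(min(3, length(ve)))]),
                    collapse = ", "),
              100 * sum(ve)))
  invisible(x)
}

#' Project histograms onto the retained components
#'
#' Centres each histogram by the decomposition mean and takes dot products
#' with the eigenvectors. Projecting the training rows reproduces the
#' stored scores.
#'
#' @param decomp a [fit_pca()] result.
#' @param histograms a `plot_histogram`, a list of them, a numeric vector of
#'   length m, or an n x m matrix.
#' @return score matrix (rows x k_retained).
#' @export
project <- function(decomp, histograms) {
  stopifnot(inherits(decomp, "histogram_decomposition"))
  H <- as_histogram_rows(histograms)
  if (ncol(H) != length(decomp$mean_histogram))
    stop("project: histogram length does not match the decomposition")
  sweep(H, 2, decomp$mean_histogram) %*% t(decomp$eigenvectors)
}

as_histogram_rows <- function(h) {
  if (inherits(h, "plot_histogram")) matrix(h$frequencies, nrow = 1)
  else if (is.list(h)) do.call(rbind, lapply(h, `[[`, "frequencies"))
  else if (is.matrix(h)) h
  else matrix(as.numeric(h), nrow = 1)
}

#' Back-projection sweep along one eigenvector
#'
#' Interprets an eigenvector by sweeping its score from the minimum to the
#' maximum observed value in `n_steps` equal steps, back-projecting each
#' score onto the eigenvector and adding back the mean histogram, with all
#' other components held at zero. The resulting model histograms show what
#' shape change the component encodes.
#'
#' @param decomp a [fit_pca()] result.
#' @param pc_index component to sweep (<= k_retained).
#' @param n_steps number of sweep points (default 5).
#' @return an object of class `back_projection_sweep`: `pc_index`,
#'   `sweep_scores` (increasing, endpoints = observed min/max), and
#'   `model_histograms` (n_steps x m).
#' @export
back_project_sweep <- function(decomp, pc_index, n_steps = 5L) {
  stopifnot(inherits(decomp, "histogram_decomposition"),
            pc_index >= 1, pc_index <= decomp$k_retained)
  s <- seq(min(decomp$scores[, pc_index]), max(decomp$scores[, pc_index]),
           length.out = n_steps)
  models <- outer(s, decomp$eigenvectors[pc_index, ]) +
    rep(decomp$mean_histogram, each = n_steps)
  structure(list(pc_index = pc_index, sweep_scores = s,
                 model_histograms = models),
            class = "back_projection_sweep")
}

#' Component-score time courses aligned to mean flowering
#'
#' Averages each genotype's component scores over trials at each flight
#' date and expresses dates relative to the mean flowering (tassel) day of
#' all genotypes in that year, which is set to day 0.
#'
#' @param decomp a [fit_pca()] result carrying `row_index`.
#' @param traits a [trait_table()] supplying tassel days for alignment.
#' @param components which components to tabulate (default 1:3).
#' @return data.frame with year, genotype_id, flight_day, relative_day,
#'   component, score.
#' @export
score_time_series <- function(decomp, traits, components = 1:3) {
  stopifnot(inherits(decomp, "histogram_decomposition"))
  ri <- decomp$row_index
  if (is.null(ri$flight_day)) stop("score_time_series: row_index lacks flight days")
  years <- unique(ri$year)
  if (!all(years %in% traits$year))
    stop("score_time_series: flowering (tassel) data missing for year(s): ",
         paste(setdiff(years, traits$year), collapse = ", "))
  mean_flower <- tapply(traits$tassel_day, traits$year, mean)
  out <- list()
  for (comp in components) {
    df <- data.frame(year = ri$year, genotype_id = ri$genotype_id,
                     flight_day = ri$flight_day,
                     score = decomp$scores[, comp])
    agg <- stats::aggregate(score ~ year + genotype_id + flight_day, df, mean)
    agg$relative_day <- agg$flight_day - as.numeric(mean_flower[agg$year])
    agg$component <- comp
    out[[length(out) + 1L]] <- agg
  }
  res <- do.call(rbind, out)
  res[order(res$component, res$year, res$genotype_id, res$flight_day),
      c("year", "genotype_id", "flight_day", "relative_day",
        "component", "score")]
}

#' Serialize / load a decomposition as a CSV set
#'
#' Writes `<prefix>_mean.csv`, `<prefix>_eigenvectors.csv`,
#' `<prefix>_eigenvalues.csv`, `<prefix>_scores.csv` and
#' `<prefix>_rows.csv` with full-precision numbers.
#'
#' @param decomp a [fit_pca()] result.
#' @param prefix file path prefix.
#' @return invisibly, the paths written.
#' @export
write_decomposition <- function(decomp, prefix) {
  stopifnot(inherits(decomp, "histogram_decomposition"))
  paths <- c(mean = paste0(prefix, "_mean.csv"),
             vec = paste0(prefix, "_eigenvectors.csv"),
             val = paste0(prefix, "_eigenvalues.csv"),
             sco = paste0(prefix, "_scores.csv"),
             row = paste0(prefix, "_rows.csv"))
  write_matrix_csv(matrix(decomp$mean_histogram, nrow = 1), paths["mean"])
  write_matrix_csv(decomp$eigenvectors, paths["vec"])
  utils::write.csv(data.frame(eigenvalue = decomp$eigenvalues,
                              variance_explained = decomp$variance_explained),
                   paths["val"], row.names = FALSE)
  write_matrix_csv(decomp$scores, paths["sco"])
  utils::write.csv(decomp$row_index, paths["row"], row.names = FALSE)
  invisible(paths)
}
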