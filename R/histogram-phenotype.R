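#' Build the histogram phenotype of one plot
#'
#' Bins a plot's BNDVI pixel values into `n_bins` (default 999) equally
#' spaced bins covering (0, 1] and normalises the counts to relative
#' frequencies (sum 1), so plots with different usable pixel counts are
#' comparable. Bins are left-open, right-closed: a value v lands in bin
#' `ceiling(v * n_bins)`; exactly 0 is out of range (dropped), exactly 1
#' falls in the last bin. Values <= 0, > 1 or `NA` are counted in
#' `n_pixels_dropped`. No canopy threshold is applied — the histogram keeps
#' sub-0.06 soil values, which is what lets PCA interpret canopy closure.
#'
#' @param pixels a [plot_pixel_set()] or numeric vector of BNDVI values.
#' @param n_bins number of bins (default 999).
#' @param normalize `"frequency"` (default; rows sum to 1 so plots with
#'   different usable pixel counts are comparable and PCA does not load on
#'   plot area) or `"count"` (raw counts, for sensitivity analysis).
#' @return an object of class `plot_histogram`: `frequencies` (length
#'   `n_bins`, sums to 1 under the default normalization), `bin_edges`
#'   (length `n_bins + 1`), `counts`, `n_pixels_used`, `n_pixels_dropped`,
#'   and plot metadata.
#' @export
#' @examples
#' h <- build_histogram(c(0.5, 0.5, 0.9), n_bins = 10)
#' h$frequencies[c(5, 9)]  # 2/3 and 1/3
build_histogram <- function(pixels, n_bins = 999L,
                            normalize = c("frequency", "count")) {
  normalize <- match.arg(normalize)
  meta <- if (inherits(pixels, "plot_pixel_set"))
    pixels[c("plot_id", "genotype_id", "trial", "flight_day", "year")]
  else list(plot_id = NA_character_, genotype_id = NA_character_,
            trial = NA_integer_, flight_day = NA_integer_, year = NA_character_)
  v <- bndvi_values_of(pixels)
  total <- length(v)
  in_range <- !is.na(v) & v > 0 & v <= 1
  if (!any(in_range))
    stop(sprintf("build_histogram: no BNDVI values in (0, 1] for plot %s, day %s",
                 meta$plot_id, format(meta$flight_day)))
  idx <- ceiling(v[in_range] * n_bins)
  idx[idx > n_bins] <- n_bins  # guard against ceiling(1 * n) float overshoot
  counts <- tabulate(idx, nbins = n_bins)
  structure(c(list(frequencies = if (normalize == "frequency")
                     counts / sum(counts) else as.numeric(counts),
                   bin_edges = seq(0, 1, length.out = n_bins + 1L),
                   counts = counts,
                   n_pixels_used = sum(in_range),
                   n_pixels_dropped = total - sum(in_range)),
              meta),
            class = "plot_histogram")
}

#' Bin centres of a histogram or decomposition
#' @param n_bins number of bins over (0, 1].
#' @return numeric vector of bin midpoints.
#' @export
bin_centers <- function(n_bins = 999L) {
  (seq_len(n_bins) - 0.5) / n_bins
}

#' Stack plot histograms into the phenotype matrix X
#'
#' Assembles one row per plot-date observation, ordered lexicographically by
#' (year, flight_day, genotype_id, trial) so the matrix is reproducible
#' regardless of input order. Missing plot-dates are simply absent: n is the
#' number of observations supplied.
#'
#' @param histograms list of [build_histogram()] results sharing `n_bins`.
#' @return an object of class `histogram_matrix`: `X` (n x m matrix of
#'   relative frequencies) and `row_index` (data.frame with genotype_id,
#'   trial, flight_day, year per row).
#' @export
stack_histograms <- function(histograms) {
  stopifnot(length(histograms) >= 1)
  m <- length(histograms[[1]]$frequencies)
  if (!all(vapply(histograms, function(h) length(h$frequencies), 1L) == m))
    stop("stack_histograms: histograms have mixed bin counts")
  idx <- data.frame(
    genotype_id = vapply(histograms, function(h) as.character(h$genotype_id), ""),
    trial = vapply(histograms, function(h) as.integer(h$trial), 1L),
    flight_day = vapply(histograms, function(h) as.numeric(h$flight_day), 1),
    year = vapply(histograms, function(h) as.character(h$year), ""),
    stringsAsFactors = FALSE
  )
  ord <- order(idx$year, idx$flight_day, idx$genotype_id, idx$trial)
  X <- do.call(rbind, lapply(histograms[ord], `[[`, "frequencies"))
  row_index <- idx[ord, , drop = FALSE]
  rownames(X) <- rownames(row_index) <- NULL
  structure(list(X = X, row_index = row_index), class = "histogram_matrix")
}

#' @export
print.histogram_matrix <- function(x, ...) {
  cat(sprintf("<histogram_matrix> %d plot-date observations x %d bins (%d year(s), %d flight day(s))\n",
              nrow(x$X), ncol(x$X), length(unique(x$row_index$year)),
              length(unique(x$row_index$flight_day))))
  invisible(x)
}

#' Write / read a histogram matrix as a CSV pair
#'
#' `<prefix>_X.csv` holds the frequency matrix with 17 significant digits
#' (lossless double round-trip); `<prefix>_rows.csv` holds the row index.
#'
#' @param hm a [stack_histograms()] result.
#' @param prefix file path prefix.
#' @return invisibly, the two paths written.
#' @export
write_histogram_matrix <- function(hm, prefix) {
  stopifnot(inherits(hm, "histogram_matrix"))
  xp <- paste0(prefix, "_X.csv")
  rp <- paste0(prefix, "_rows.csv")
  write_matrix_csv(hm$X, xp)
  utils::write.csv(hm$row_index, rp, row.names = FALSE)
  invisible(c(xp, rp))
}

#' @rdname write_histogram_matrix
#' @param prefix file path prefix used when writing.
#' @export
read_histogram_matrix <- function(prefix) {
  X <- read_matrix_csv(paste0(prefix, "_X.csv"))
  row_index <- utils::read.csv(paste0(prefix, "_rows.csv"),
                               stringsAsFactors = FALSE)
  structure(list(X = X, row_index = row_index), class = "histogram_matrix")
}

#' Subset a histogram matrix by year
#'
#' Convenience for per-year sensitivity analyses (fitting the decomposition
#' on one year instead of all years jointly).
#'
#' @param hm a [stack_histograms()] result.
#' @param years year label(s) to keep.
#' @return a `histogram_matrix` with the matching rows.
#' @export
subset_histogram_matrix <- function(hm, years) {
  keep <- hm$row_index$year %in% years
  if (!any(keep)) stop("subset_histogram_matrix: no rows for the given year(s)")
  structure(list(X = hm$X[keep, , drop = FALSE],
                 row_index = hm$row_index[keep, , drop = FALSE]),
            class = "histogram_matrix")
}

# full-precision numeric matrix CSV helpers (17 significant digits)
write_matrix_csv <- function(X, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(sprintf("b%04d", seq_len(ncol(X))), collapse = ","), con)
  for (i in seq_len(nrow(X)))
    writeLines(paste(sprintf("%.17g", X[i, ]), collapse = ","), con)
  invisible(path)
}

read_matrix_csv <- function(path) {
  as.matrix(utils::read.csv(path, colClasses = "numeric"))
}
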