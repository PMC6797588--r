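#' Construct a trait table
#'
#' One row per genotype x trial (x year): manually measured agronomic
#' traits — tassel date and silk date (day-of-season on which 50% of plants
#' in the plot shed pollen / show silks), grain yield (kg/plot), and kernel
#' length, width and thickness (mm). Validates positivity of yield and
#' warns (without erroring) when silk precedes tassel, which field data can
#' legitimately contain.
#'
#' @param df data.frame with columns genotype_id, trial, year, tassel_day,
#'   silk_day, yield_kg, kernel_length, kernel_width, kernel_thickness.
#' @return the validated data.frame with class `trait_table`.
#' @export
trait_table <- function(df) {
  needed <- c("genotype_id", "trial", "year", "tassel_day", "silk_day",
              "yield_kg", "kernel_length", "kernel_width", "kernel_thickness")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("trait_table: missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(df$yield_kg <= 0)) stop("trait_table: yield_kg must be positive")
  key <- paste(df$genotype_id, df$trial, df$year)
  if (anyDuplicated(key))
    stop("trait_table: duplicated genotype x trial x year rows")
  n_rev <- sum(df$silk_day < df$tassel_day, na.rm = TRUE)
  if (n_rev > 0)
    warning(sprintf("trait_table: %d row(s) with silk_day < tassel_day", n_rev))
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Read a trait table from CSV
#' @param path CSV with the [trait_table()] columns.
#' @return a `trait_table`.
#' @export
read_trait_table <- function(path) {
  trait_table(utils::read.csv(path, stringsAsFactors = FALSE))
}
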