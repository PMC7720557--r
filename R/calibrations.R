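# Tip calibration tables: stratigraphic age ranges (Ma) per taxon.

#' Build a calibration table
#'
#' Each fossil tip gets a uniform age prior on its stratigraphic range
#' `[age_min, age_max]` (Ma before present); extant taxa have
#' `age_min = age_max = 0`.
#'
#' @param taxon character vector of taxon labels.
#' @param age_min,age_max numeric vectors, Ma; `0 <= age_min <= age_max`.
#' @return a `calibration_table` data frame with columns `taxon`, `age_min`,
#'   `age_max`, `is_extant`.
#' @export
calibration_table <- function(taxon, age_min, age_max) {
  taxon <- as.character(taxon)
  age_min <- as.numeric(age_min); age_max <- as.numeric(age_max)
  if (length(taxon) != length(age_min) || length(taxon) != length(age_max))
    stop2("taxon/age_min/age_max lengths differ")
  if (anyDuplicated(taxon)) stop2("duplicate taxon in calibration table")
  bad <- which(age_min > age_max | age_min < 0)
  if (length(bad))
    stop2("invalid age range for ", paste(taxon[bad], collapse = ", "),
          " (need 0 <= min <= max)")
  out <- data.frame(taxon = taxon, age_min = age_min, age_max = age_max,
                    is_extant = age_min == 0 & age_max == 0,
                    stringsAsFactors = FALSE)
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' Read a calibration table from CSV
#'
#' @param path CSV with columns `taxon`, `age_min`, `age_max` (Ma).
#' @param matrix_taxa optional vector of taxon labels to cross-check against.
#' @return a [calibration_table()].
#' @export
read_calibrations <- function(path, matrix_taxa = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon", "age_min", "age_max")
  if (!all(need %in% names(df)))
    stop2("calibration file must have columns: ", paste(need, collapse = ", "))
  out <- calibration_table(df$taxon, df$age_min, df$age_max)
  if (!is.null(matrix_taxa)) {
    missing <- setdiff(out$taxon, matrix_taxa)
    if (length(missing))
      stop2("calibrated taxa absent from matrix: ", paste(missing, collapse = ", "))
  }
  out
}

#' Write a calibration table to CSV
#' @param x a [calibration_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibrations <- function(x, path) {
  utils::write.csv(x[, c("taxon", "age_min", "age_max")], path, row.names = FALSE)
  invisible(path)
}
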