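#' Species-specific egg-volume constants
#'
#' Returns the dimensionless constants \eqn{\beta} used in the egg-volume
#' formula \eqn{V = \beta L W^2}, with length and width in millimetres and
#' volume in cubic centimetres: 0.476e-3 for the yellow-legged gull and
#' 0.509e-3 for Scopoli's shearwater.
#'
#' @return Named numeric vector with elements `gull` and `shearwater`.
#' @export
#' @examples
#' species_constants()
species_constants <- function() {
  c(gull = 0.476e-3, shearwater = 0.509e-3)
}

#' Egg volume from linear measurements
#'
#' Computes \eqn{V = \beta L W^2} in cm^3 from egg length and width in mm.
#'
#' @param length_mm Egg length in millimetres, > 0.
#' @param width_mm Egg width (maximum breadth) in millimetres, > 0.
#' @param beta Species-specific volume constant, > 0 (see
#'   [species_constants()]).
#' @return Numeric vector of volumes in cm^3.
#' @export
#' @examples
#' egg_volume(70, 50, species_constants()["gull"])
egg_volume <- function(length_mm, width_mm, beta) {
  if (any(!is.finite(length_mm)) || any(length_mm <= 0))
    stop_eggsync("length_mm must be finite and > 0", "eggsync_invalid_measurement")
  if (any(!is.finite(width_mm)) || any(width_mm <= 0))
    stop_eggsync("width_mm must be finite and > 0", "eggsync_invalid_measurement")
  if (any(!is.finite(beta)) || any(beta <= 0))
    stop_eggsync("beta must be finite and > 0", "eggsync_invalid_measurement")
  beta * length_mm * width_mm^2
}

validate_egg_records <- function(records, autoswap = FALSE) {
  needed <- c("species", "year", "nest_id", "length_mm", "width_mm")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop_eggsync(sprintf("egg records lack column(s): %s",
                         paste(missing, collapse = ", ")),
                 "eggsync_schema_error")
  bad_sp <- setdiff(unique(as.character(records$species)),
                    names(species_constants()))
  if (length(bad_sp))
    stop_eggsync(sprintf("unknown species label(s): %s",
                         paste(bad_sp, collapse = ", ")),
                 "eggsync_schema_error")
  swapped <- which(records$width_mm > records$length_mm)
  if (length(swapped)) {
    if (autoswap) {
      tmp <- records$length_mm[swapped]
      records$length_mm[swapped] <- records$width_mm[swapped]
      records$width_mm[swapped] <- tmp
      warning(sprintf("%d record(s) had width > length; measurements swapped",
                      length(swapped)))
    } else {
      warning(sprintf(
        "%d record(s) have width > length (possible transcription swap), e.g. row %d",
        length(swapped), swapped[1]))
    }
  }
  records
}

#' Read egg morphometry records from CSV
#'
#' Expects the header `species,year,nest_id,length_mm,width_mm` with species
#' in `{gull, shearwater}`.  Malformed files raise a schema error naming the
#' offending column or row.
#'
#' @param path Path to the CSV file.
#' @param autoswap Swap length/width where width > length (calliper
#'   transcription errors) instead of only warning.  Default `FALSE`.
#' @return A data frame of egg records.
#' @export
read_eggs_csv <- function(path, autoswap = FALSE) {
  if (!file.exists(path))
    stop_eggsync(sprintf("eggs CSV not found: %s", path), "eggsync_io_error")
  records <- read.csv(path, stringsAsFactors = FALSE)
  records <- validate_egg_records(records, autoswap = autoswap)
  for (col in c("year", "length_mm", "width_mm")) {
    v <- records[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop_eggsync(sprintf("column %s is not numeric (first bad row: %s)",
                           col, ifelse(is.na(bad), "?", bad)),
                   "eggsync_schema_error")
    }
    if (anyNA(v))
      stop_eggsync(sprintf("column %s contains missing values (row %d)",
                           col, which(is.na(v))[1]),
                   "eggsync_schema_error")
  }
  records$species <- as.character(records$species)
  records
}

#' Annual mean egg-volume series per species
#'
#' Converts egg records into one contiguous annual series of mean egg volume
#' per species.  Volumes are aggregated clutch-first: eggs are averaged
#' within `nest_id` x `year` (the clutch mean), then clutch means are
#' averaged within year.  Set `clutch_first = FALSE` to pool eggs directly.
#'
#' @param records Data frame of egg records (see [read_eggs_csv()]).
#' @param constants Named vector of per-species volume constants; defaults to
#'   the published pair ([species_constants()]).
#' @param study_window Optional `c(first_year, last_year)`.  Records outside
#'   it are an error; a year inside it with no clutches for a species is an
#'   error because the synchrony analysis needs contiguous series.
#' @param clutch_first Aggregate eggs to clutch means before the annual mean
#'   (default `TRUE`).
#' @param autoswap See [read_eggs_csv()].
#' @return A data frame of class `annual_series` with columns `species`,
#'   `year`, `mean_volume_cm3`, `n_clutches`, `sd_volume_cm3` (SD of clutch
#'   means within the year).
#' @export
annual_series <- function(records, constants = species_constants(),
                          study_window = NULL, clutch_first = TRUE,
                          autoswap = FALSE) {
  records <- validate_egg_records(records, autoswap = autoswap)
  if (!nrow(records))
    stop_eggsync("no egg records", "eggsync_empty_input")
  if (any(constants <= 0))
    stop_eggsync("volume constants must be > 0", "eggsync_invalid_measurement")
  if (!is.null(study_window)) {
    lo <- study_window[1]; hi <- study_window[2]
    out <- records$year < lo | records$year > hi
    if (any(out))
      stop_eggsync(sprintf("%d record(s) outside study window %d-%d",
                           sum(out), lo, hi),
                   "eggsync_window_error")
  }
  records$volume_cm3 <- egg_volume(records$length_mm, records$width_mm,
                                   unname(constants[records$species]))
  pieces <- lapply(split(records, records$species), function(df) {
    if (clutch_first) {
      cl <- aggregate(volume_cm3 ~ year + nest_id, data = df, FUN = mean)
    } else {
      cl <- df[, c("year", "nest_id", "volume_cm3")]
    }
    ann <- aggregate(volume_cm3 ~ year, data = cl, FUN = mean)
    nn <- aggregate(volume_cm3 ~ year, data = cl, FUN = length)
    ss <- aggregate(volume_cm3 ~ year, data = cl,
                    FUN = function(v) if (length(v) > 1) sd(v) else NA_real_)
    out <- data.frame(species = df$species[1], year = ann$year,
                      mean_volume_cm3 = ann$volume_cm3,
                      n_clutches = nn$volume_cm3,
                      sd_volume_cm3 = ss$volume_cm3)
    out <- out[order(out$year), ]
    span <- if (is.null(study_window)) range(out$year) else study_window
    want <- seq(span[1], span[2])
    gap <- setdiff(want, out$year)
    if (length(gap))
      stop_eggsync(sprintf("species %s has no clutches in year(s) %s; the synchrony analysis requires contiguous series",
                           df$species[1], paste(gap, collapse = ", ")),
                   "eggsync_missing_year")
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("annual_series", "data.frame")
  out
}

#' Write / read annual series CSV
#'
#' The series CSV has the header
#' `species,year,mean_volume_cm3,n_clutches,sd_volume_cm3`; the write/read
#' round trip preserves values to full stored precision.
#'
#' @param series An `annual_series` data frame.
#' @param path Output path.
#' @return `write_series_csv` returns `path` invisibly; `read_series_csv`
#'   returns the `annual_series` data frame.
#' @export
write_series_csv <- function(series, path) {
  cols <- c("species", "year", "mean_volume_cm3", "n_clutches", "sd_volume_cm3")
  missing <- setdiff(cols, names(series))
  if (length(missing))
    stop_eggsync(sprintf("series lacks column(s): %s",
                         paste(missing, collapse = ", ")),
                 "eggsync_schema_error")
  write.csv(format(series[, cols], digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path))
    stop_eggsync(sprintf("series CSV not found: %s", path), "eggsync_io_error")
  out <- read.csv(path, stringsAsFactors = FALSE)
  cols <- c("species", "year", "mean_volume_cm3", "n_clutches", "sd_volume_cm3")
  missing <- setdiff(cols, names(out))
  if (length(missing))
    stop_eggsync(sprintf("series CSV lacks column(s): %s",
                         paste(missing, collapse = ", ")),
                 "eggsync_schema_error")
  class(out) <- c("annual_series", "data.frame")
  out
}

# internal: pull one species' (year, value) out of whatever series
# representation a caller hands us
series_values <- function(x, species = NULL) {
  if (inherits(x, "annual_series") || is.data.frame(x)) {
    if (!is.null(species) && "species" %in% names(x))
      x <- x[x$species == species, ]
    if (!is.null(x$species) && length(unique(x$species)) > 1)
      stop_eggsync("series contains several species; pass `species`",
                   "eggsync_schema_error")
    ord <- order(x$year)
    list(years = as.integer(x$year[ord]), values = x$mean_volume_cm3[ord])
  } else if (is.numeric(x)) {
    yrs <- attr(x, "years")
    if (is.null(yrs)) yrs <- seq_along(x)
    list(years = as.integer(yrs), values = as.numeric(x))
  } else {
    stop_eggsync("cannot interpret series input", "eggsync_schema_error")
  }
}
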