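# Domain types and CSV input/output for stations, daily temperatures and
# phenology observation series, plus the data-cleaning rules applied to
# phenology records before model fitting.

#' Climate zone levels, ordered from north to south
#'
#' The six study-area climate zones (plus a catch-all) in geographic
#' order, middle temperate (northernmost) to north tropical
#' (southernmost). Zone frequency summaries report rows in this order.
#'
#' @return Character vector of zone labels.
#' @export
climate_zones <- function() {
  c("middle_temperate", "warm_temperate", "north_subtropical",
    "middle_subtropical", "south_subtropical", "north_tropical", "other")
}

#' Phenophase labels
#' @return Character vector of the two supported phenophases.
#' @export
phenophases <- function() {
  c("first_leaf_unfolding", "first_flowering")
}

#' Construct a station record table
#'
#' @param station_id Character vector of unique station identifiers.
#' @param latitude Degrees north, in \[-90, 90\].
#' @param longitude Degrees east.
#' @param elevation Metres above sea level.
#' @param climate_zone One of [climate_zones()] per station.
#' @return A `data.frame` with class `station_table`.
#' @export
station_table <- function(station_id, latitude, longitude = NA_real_,
                          elevation = NA_real_,
                          climate_zone = "other") {
  station_id <- as.character(station_id)
  if (any(!nzchar(station_id)) || anyNA(station_id))
    stop("station_id must be non-empty")
  if (anyDuplicated(station_id))
    stop("station_id must be unique within a dataset")
  if (any(latitude < -90 | latitude > 90))
    stop("latitude must lie in [-90, 90]")
  climate_zone <- as.character(climate_zone)
  bad <- !climate_zone %in% climate_zones()
  if (any(bad))
    stop("unknown climate_zone: ", paste(unique(climate_zone[bad]), collapse = ", "))
  out <- data.frame(
    station_id = station_id,
    latitude = as.numeric(latitude),
    longitude = rep_len(as.numeric(longitude), length(station_id)),
    elevation = rep_len(as.numeric(elevation), length(station_id)),
    climate_zone = rep_len(climate_zone, length(station_id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("station_table", "data.frame")
  out
}

#' Construct a daily mean temperature series
#'
#' A contiguous, date-indexed series of daily mean air temperature for
#' one station. Values must be finite and cover consecutive calendar
#' days starting at `start_date`.
#'
#' @param station_id Station identifier.
#' @param start_date Date of the first value.
#' @param values Numeric vector of daily mean temperatures, degrees C.
#' @return An object of class `daily_temperature_series`.
#' @export
daily_temperature_series <- function(station_id, start_date, values) {
  start_date <- as.Date(start_date)
  values <- as.numeric(values)
  if (length(values) < 1L) stop("empty temperature series")
  if (any(!is.finite(values))) stop("temperature values must be finite")
  structure(
    list(station_id = as.character(station_id),
         start_date = start_date,
         values = values),
    class = "daily_temperature_series"
  )
}

#' @export
print.daily_temperature_series <- function(x, ...) {
  cat(sprintf("<daily_temperature_series> station %s: %d days, %s .. %s\n",
              x$station_id, length(x$values),
              format(x$start_date), format(series_end_date(x))))
  invisible(x)
}

#' Last date covered by a temperature series
#' @param series A `daily_temperature_series`.
#' @return A `Date`.
#' @export
series_end_date <- function(series) {
  series$start_date + (length(series$values) - 1L)
}

#' Extract temperatures for a date window
#'
#' @param series A `daily_temperature_series`.
#' @param from,to Dates, inclusive.
#' @return Numeric vector of daily values, one per day of the window.
#' @export
temperature_window <- function(series, from, to) {
  from <- as.Date(from); to <- as.Date(to)
  if (from < series$start_date || to > series_end_date(series))
    stop(sprintf("series %s does not cover %s .. %s (coverage %s .. %s)",
                 series$station_id, format(from), format(to),
                 format(series$start_date), format(series_end_date(series))))
  i0 <- as.integer(from - series$start_date) + 1L
  i1 <- as.integer(to - series$start_date) + 1L
  series$values[i0:i1]
}

#' Construct a phenology observation series
#'
#' Observed event dates (day-of-year, Jan 1 = 1) for one
#' station-species-phenophase combination, indexed by year.
#'
#' @param station_id Station identifier.
#' @param species Species name.
#' @param phenophase One of [phenophases()].
#' @param years Integer vector of observation years, strictly increasing.
#' @param doy Integer day-of-year per year, in \[1, 366\].
#' @return An object of class `phenology_series`.
#' @export
phenology_series <- function(station_id, species, phenophase, years, doy) {
  years <- as.integer(years)
  doy <- as.numeric(doy)
  if (length(years) != length(doy)) stop("years and doy differ in length")
  if (is.unsorted(years, strictly = TRUE)) stop("years must be strictly increasing")
  if (any(doy < 1 | doy > 366)) stop("day-of-year outside [1, 366]")
  if (!phenophase %in% phenophases())
    stop("phenophase must be one of: ", paste(phenophases(), collapse = ", "))
  structure(
    list(station_id = as.character(station_id),
         species = as.character(species),
         phenophase = phenophase,
         years = years,
         doy = doy),
    class = "phenology_series"
  )
}

#' @export
print.phenology_series <- function(x, ...) {
  cat(sprintf("<phenology_series> %s / %s / %s: %d years (%d-%d), mean DOY %.1f\n",
              x$station_id, x$species, x$phenophase, length(x$years),
              min(x$years), max(x$years), mean(x$doy)))
  invisible(x)
}

#' @export
length.phenology_series <- function(x) length(x$years)

# ---- CSV readers / writers -------------------------------------------------

#' Read a daily temperature CSV
#'
#' Expects columns `station_id,date,tmean` with ISO-8601 dates. Dates
#' must be consecutive; gaps of up to `max_gap` days are filled by
#' linear interpolation when `fill_gaps = TRUE`, and any larger gap is
#' an error.
#'
#' @param path Path to the CSV file.
#' @param fill_gaps Interpolate gaps of at most `max_gap` days?
#' @param max_gap Largest gap (missing days) interpolation may bridge.
#' @return A `daily_temperature_series`. When gaps were filled, the
#'   attribute `"fill_log"` records the interpolated dates.
#' @export
read_temperature_csv <- function(path, fill_gaps = FALSE, max_gap = 3L) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "date", "tmean")
  if (!all(need %in% names(df)))
    stop("temperature CSV must have columns: ", paste(need, collapse = ","))
  if (length(unique(df$station_id)) != 1L)
    stop("temperature CSV must contain a single station")
  dates <- as.Date(df$date)
  if (anyNA(dates)) stop("unparseable date in temperature CSV")
  o <- order(dates)
  dates <- dates[o]; tmean <- as.numeric(df$tmean[o])
  dd <- as.integer(diff(dates))
  if (any(dd == 0L)) stop("duplicated date in temperature CSV")
  fill_log <- character(0)
  if (any(dd > 1L)) {
    gaps <- dd - 1L
    if (any(gaps > max_gap))
      stop(sprintf("temperature series has a gap of %d days (> %d)",
                   max(gaps), max_gap))
    if (!fill_gaps)
      stop("temperature series has gaps; set fill_gaps = TRUE to interpolate")
    full <- seq(dates[1L], dates[length(dates)], by = "day")
    filled <- approx(x = as.numeric(dates), y = tmean,
                     xout = as.numeric(full), method = "linear")$y
    fill_log <- format(full[!full %in% dates])
    dates <- full; tmean <- filled
  }
  out <- daily_temperature_series(df$station_id[1L], dates[1L], tmean)
  attr(out, "fill_log") <- fill_log
  out
}

#' Write a daily temperature CSV
#' @param series A `daily_temperature_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_temperature_csv <- function(series, path) {
  dates <- seq(series$start_date, by = "day", length.out = length(series$values))
  df <- data.frame(station_id = series$station_id,
                   date = format(dates, "%Y-%m-%d"),
                   tmean = series$values)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenology observation CSV
#'
#' Expects columns `station_id,species,phenophase,year,doy`; one
#' [phenology_series] is returned per unique
#' (station, species, phenophase) combination.
#'
#' @param path Path to the CSV file.
#' @return A list of `phenology_series`.
#' @export
read_phenology_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "species", "phenophase", "year", "doy")
  if (!all(need %in% names(df)))
    stop("phenology CSV must have columns: ", paste(need, collapse = ","))
  if (any(df$doy < 1 | df$doy > 366))
    stop("day-of-year outside [1, 366] in phenology CSV")
  key <- interaction(df$station_id, df$species, df$phenophase, drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$year), , drop = FALSE]
    phenology_series(g$station_id[1L], g$species[1L], g$phenophase[1L],
                     g$year, g$doy)
  })
}

#' Write phenology series to CSV
#' @param series_list A `phenology_series` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenology_csv <- function(series_list, path) {
  if (inherits(series_list, "phenology_series")) series_list <- list(series_list)
  df <- do.call(rbind, lapply(series_list, function(s)
    data.frame(station_id = s$station_id, species = s$species,
               phenophase = s$phenophase, year = s$years, doy = s$doy)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a station metadata CSV
#'
#' Expects columns `station_id,lat,lon,elev,zone`.
#'
#' @param path Path to the CSV file.
#' @return A [station_table].
#' @export
read_stations_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "lat", "lon", "elev", "zone")
  if (!all(need %in% names(df)))
    stop("stations CSV must have columns: ", paste(need, collapse = ","))
  station_table(df$station_id, df$lat, df$lon, df$elev, df$zone)
}

#' Write a station metadata CSV
#' @param stations A [station_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stations_csv <- function(stations, path) {
  df <- data.frame(station_id = stations$station_id, lat = stations$latitude,
                   lon = stations$longitude, elev = stations$elevation,
                   zone = stations$climate_zone)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- Cleaning --------------------------------------------------------------

#' Remove phenology outliers beyond two standard deviations
#'
#' Single-pass screening: the mean and sample standard deviation
#' (n - 1 denominator) are computed once on the full input series, and
#' every observation farther than `n_sd` standard deviations from that
#' mean is dropped. Statistics are not recomputed after removals, so
#' re-applying the rule with the original statistics changes nothing.
#'
#' @param series A [phenology_series] of length >= 3.
#' @param n_sd Number of standard deviations defining an outlier.
#' @return A list with elements `series` (the cleaned
#'   `phenology_series`) and `report` (a `cleaning_report` list with
#'   `removed_outliers` (data.frame year/value), `n_before`, `n_after`).
#' @export
remove_outliers <- function(series, n_sd = 2) {
  stopifnot(inherits(series, "phenology_series"))
  if (length(series) < 3L) stop("series too short for outlier screening (< 3)")
  m <- mean(series$doy)
  s <- sd(series$doy)
  keep <- if (s == 0) rep(TRUE, length(series)) else abs(series$doy - m) <= n_sd * s
  removed <- data.frame(year = series$years[!keep], value = series$doy[!keep])
  cleaned <- series
  cleaned$years <- series$years[keep]
  cleaned$doy <- series$doy[keep]
  report <- structure(
    list(removed_outliers = removed,
         n_before = length(series),
         n_after = sum(keep),
         mean = m, sd = s, n_sd = n_sd),
    class = "cleaning_report"
  )
  list(series = cleaned, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("<cleaning_report> %d -> %d observations (%d outliers removed)\n",
              x$n_before, x$n_after, nrow(x$removed_outliers)))
  invisible(x)
}

#' Reject series shorter than a minimum number of years
#'
#' @param series A [phenology_series] (normally after [remove_outliers]).
#' @param min_years Minimum retained length; shorter series are rejected.
#' @return The series if it has at least `min_years` observations,
#'   otherwise `NULL`.
#' @export
filter_min_length <- function(series, min_years = 10L) {
  if (length(series) >= min_years) series else NULL
}

#' Clean a phenology series: outlier screening then length filter
#'
#' Applies [remove_outliers] followed by [filter_min_length], in that
#' order.
#'
#' @inheritParams remove_outliers
#' @inheritParams filter_min_length
#' @return A list with `series` (cleaned series or `NULL` if rejected)
#'   and `report` (the `cleaning_report`, with an added logical
#'   `removed_short_series`).
#' @export
clean_phenology_series <- function(series, n_sd = 2, min_years = 10L) {
  res <- remove_outliers(series, n_sd = n_sd)
  kept <- filter_min_length(res$series, min_years = min_years)
  res$report$removed_short_series <- is.null(kept)
  list(series = kept, report = res$report)
}

#' Serialize a cleaning report to JSON
#' @param report A `cleaning_report`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string, or `path` invisibly when written to file.
#' @export
cleaning_report_json <- function(report, path = NULL) {
  obj <- list(
    n_before = report$n_before,
    n_after = report$n_after,
    removed_outliers = report$removed_outliers,
    removed_short_series = isTRUE(report$removed_short_series)
  )
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
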