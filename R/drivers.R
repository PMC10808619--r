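# Photoperiod and derived climate metrics: Forsythe daylength, winter
# temperature, winter duration, and spring temperature variation.

#' Daylength from latitude and day of year (Forsythe revised-Schoolfield)
#'
#' Computes daylength in hours from the solar declination (via the
#' day-angle approximation) and the hour-angle arccosine, with a
#' daylength coefficient `p` (degrees of solar elevation below the
#' horizon at which day begins/ends). The default `p = 0.8333` counts
#' the day from when the top of the solar disc, refracted, touches the
#' horizon (the civil sunrise/sunset definition); `p = 0` gives the
#' geometric centre-of-sun daylength. The arccosine argument is clamped
#' to \[-1, 1\] so polar day/night return 24 h or 0 h rather than NaN.
#'
#' @param latitude Degrees north (negative south).
#' @param doy Day of year (Jan 1 = 1); vectorised.
#' @param p Daylength coefficient, degrees; in \[-6, 18\].
#' @return Daylength in hours, in \[0, 24\].
#' @export
daylength <- function(latitude, doy, p = 0.8333) {
  stopifnot(p >= -6, p <= 18)
  theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (doy - 186)))
  phi <- asin(0.39795 * cos(theta))            # solar declination, radians
  lat <- latitude * pi / 180
  a <- (sin(p * pi / 180) + sin(lat) * sin(phi)) / (cos(lat) * cos(phi))
  a <- pmin(1, pmax(-1, a))
  24 - (24 / pi) * acos(a)
}

# Day-of-year for a (year, doy) pair as a calendar Date (Jan 1 = DOY 1).
doy_to_date <- function(year, doy) {
  as.Date(sprintf("%d-01-01", year)) + (doy - 1L)
}

# DOY of a Date within a reference year; dates before Jan 1 of ref_year
# get values <= 0 (Dec 31 of the previous year is 0).
date_to_doy <- function(date, ref_year) {
  as.integer(date - as.Date(sprintf("%d-01-01", ref_year))) + 1L
}

#' Multiyear mean winter (Dec-Feb) temperature
#'
#' For each phenology year, averages daily mean temperature from
#' December 1st of the previous year through the last day of February,
#' then averages across years. All Dec-Feb days are weighted equally,
#' so the result equals the grand mean over all winter days.
#'
#' @param temps A [daily_temperature_series] covering every window.
#' @param years Integer vector of phenology years.
#' @return Mean winter temperature, degrees C.
#' @export
winter_temperature <- function(temps, years) {
  vals <- unlist(lapply(years, function(y) {
    from <- as.Date(sprintf("%d-12-01", y - 1L))
    to <- as.Date(sprintf("%d-03-01", y)) - 1L
    temperature_window(temps, from, to)
  }))
  mean(vals)
}

#' Multiyear mean winter duration
#'
#' For each phenology year, counts days with mean temperature strictly
#' below `threshold` between November 1st of the previous year and the
#' multiyear mean phenology date (inclusive), then averages the count
#' across years.
#'
#' @param temps A [daily_temperature_series].
#' @param mean_phenology_doy Multiyear mean event day-of-year.
#' @param years Integer vector of phenology years.
#' @param threshold Cold-day threshold, degrees C.
#' @return Mean number of cold days per winter.
#' @export
winter_duration <- function(temps, mean_phenology_doy, years, threshold = 5) {
  counts <- vapply(years, function(y) {
    from <- as.Date(sprintf("%d-11-01", y - 1L))
    to <- doy_to_date(y, round(mean_phenology_doy))
    sum(temperature_window(temps, from, to) < threshold)
  }, numeric(1))
  mean(counts)
}

#' Multiyear mean spring temperature variation
#'
#' For each phenology year, takes the 60-day temperature window ending
#' the day before the multiyear mean phenology date, removes a
#' least-squares linear trend in day index, and computes the sample
#' standard deviation of the residuals; the per-year standard
#' deviations are then averaged.
#'
#' @inheritParams winter_duration
#' @param window_days Window length in days preceding the mean date.
#' @return Mean detrended standard deviation, degrees C.
#' @export
spring_temperature_variation <- function(temps, mean_phenology_doy, years,
                                         window_days = 60L) {
  sds <- vapply(years, function(y) {
    to <- doy_to_date(y, round(mean_phenology_doy)) - 1L
    from <- to - (window_days - 1L)
    v <- temperature_window(temps, from, to)
    idx <- seq_along(v)
    sd(residuals(lm(v ~ idx)))
  }, numeric(1))
  mean(sds)
}

#' Derived climate metrics for a station-series pair
#'
#' Convenience wrapper computing winter temperature, winter duration
#' and spring temperature variation relative to the mean observed
#' phenology date of a series.
#'
#' @param temps A [daily_temperature_series].
#' @param series A [phenology_series].
#' @return A list with `winter_temperature`, `winter_duration`,
#'   `spring_temperature_variation` and `mean_phenology_doy`.
#' @export
climate_metrics <- function(temps, series) {
  mdoy <- mean(series$doy)
  list(
    winter_temperature = winter_temperature(temps, series$years),
    winter_duration = winter_duration(temps, mdoy, series$years),
    spring_temperature_variation =
      spring_temperature_variation(temps, mdoy, series$years),
    mean_phenology_doy = mdoy
  )
}
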