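# Synthetic weather and phenology generation with known ground truth:
# a seasonal-sinusoid + AR(1) daily temperature model and forward-model
# phenology observations with observation noise, scaled up to a
# latitude-gradient station network.

#' Synthetic daily-weather configuration
#'
#' Daily mean temperature is modelled as
#' `T(d) = annual_mean - seasonal_amplitude * cos(2*pi*(d - phase_doy + 182.5) / 365.25) + e(d)`
#' where `d` indexes days, the cosine peaks at `phase_doy`, and `e` is
#' a stationary AR(1) process with lag-1 autocorrelation `ar1_rho` and
#' marginal standard deviation `noise_sd` (the innovation SD is
#' `noise_sd * sqrt(1 - ar1_rho^2)`).
#'
#' Defaults emulate a mid-latitude East Asian monsoon station: annual
#' mean 10 degrees C, seasonal amplitude 14 degrees C, warmest day in
#' mid-July (DOY 197), day-to-day autocorrelation 0.7, marginal noise
#' SD 3 degrees C, and a 34-year record (1981-2014).
#'
#' @param annual_mean Annual mean temperature, degrees C.
#' @param seasonal_amplitude Half the seasonal range, degrees C.
#' @param phase_doy Day-of-year of the climatological maximum.
#' @param ar1_rho Lag-1 autocorrelation of the noise, in \[0, 1).
#' @param noise_sd Marginal (stationary) noise SD, degrees C.
#' @param years Integer vector of phenology years to cover; the series
#'   starts January 1st of the year before the first one.
#' @param rng_seed Integer seed.
#' @return A list of class `weather_gen_config`.
#' @export
weather_gen_config <- function(annual_mean = 10, seasonal_amplitude = 14,
                               phase_doy = 197, ar1_rho = 0.7, noise_sd = 3,
                               years = 1981:2014, rng_seed = 1L) {
  stopifnot(noise_sd >= 0, ar1_rho >= 0, ar1_rho < 1,
            seasonal_amplitude >= 0, length(years) >= 1)
  structure(
    list(annual_mean = annual_mean, seasonal_amplitude = seasonal_amplitude,
         phase_doy = phase_doy, ar1_rho = ar1_rho, noise_sd = noise_sd,
         years = as.integer(years), rng_seed = as.integer(rng_seed)),
    class = "weather_gen_config"
  )
}

#' Generate a synthetic daily temperature series
#'
#' Produces a contiguous daily series from January 1st of the year
#' preceding `min(config$years)` (so the previous-winter coverage the
#' phenology models need is always present) through December 31st of
#' `max(config$years)`. Reproducible given `config$rng_seed`.
#'
#' @param config A [weather_gen_config()].
#' @param station_id Station identifier for the series.
#' @return A [daily_temperature_series].
#' @export
generate_temperature <- function(config, station_id = "SYN001") {
  start <- as.Date(sprintf("%d-01-01", min(config$years) - 1L))
  end <- as.Date(sprintf("%d-12-31", max(config$years)))
  dates <- seq(start, end, by = "day")
  d <- as.numeric(dates - start) + 1
  seasonal <- config$annual_mean - config$seasonal_amplitude *
    cos(2 * pi * (d - config$phase_doy + 182.5) / 365.25)
  noise <- with_rng_seed(config$rng_seed, {
    n <- length(d)
    if (config$noise_sd == 0) {
      numeric(n)
    } else {
      innov_sd <- config$noise_sd * sqrt(1 - config$ar1_rho^2)
      e <- numeric(n)
      e[1] <- rnorm(1, 0, config$noise_sd)
      z <- rnorm(n - 1, 0, innov_sd)
      for (i in 2:n) e[i] <- config$ar1_rho * e[i - 1] + z[i - 1]
      e
    }
  })
  daily_temperature_series(station_id, start, seasonal + noise)
}

#' Ground truth for synthetic phenology
#'
#' Bundles the generating forward model with the observation-noise
#' settings, so recovery tests can compare fits against the truth.
#' `observation_grid = "every_other_day"` snaps observed dates to an
#' alternate-day visiting schedule (odd days of year), emulating
#' networks where observers visit every second day.
#'
#' @param params A `model_parameters` object (the generating model).
#' @param observation_noise_sd Observation noise SD, days.
#' @param observation_grid `"daily"` or `"every_other_day"`.
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(params, observation_noise_sd = 1,
                            observation_grid = c("daily", "every_other_day")) {
  stopifnot(inherits(params, "model_parameters"), observation_noise_sd >= 0)
  observation_grid <- match.arg(observation_grid)
  structure(
    list(params = params, observation_noise_sd = observation_noise_sd,
         observation_grid = observation_grid),
    class = "synthetic_truth"
  )
}

#' Generate synthetic phenology observations from a known truth
#'
#' Runs the generating model forward for each year, adds rounded
#' Gaussian observation noise, and (for the every-other-day grid)
#' snaps each date to the nearest odd day of year. Years in which the
#' model predicts no event are dropped with a warning, mirroring field
#' practice of recording a date only when the event is seen.
#'
#' @param truth A [synthetic_truth()].
#' @param temps A [daily_temperature_series] covering the years.
#' @param latitude Station latitude, degrees north.
#' @param years Integer vector of phenology years.
#' @param rng_seed Integer seed for the observation noise.
#' @param station_id,species,phenophase Labels for the output series.
#' @param p Daylength coefficient.
#' @return A [phenology_series]; the noise-free generating dates are
#'   stored in attribute `"true_doy"` (named by year).
#' @export
generate_phenology <- function(truth, temps, latitude, years, rng_seed = 1L,
                               station_id = temps$station_id,
                               species = "synthetic_species",
                               phenophase = "first_leaf_unfolding",
                               p = 0.8333) {
  stopifnot(inherits(truth, "synthetic_truth"))
  true_doy <- predict_series(truth$params, temps, latitude, years, p = p)
  occ <- !is.na(true_doy)
  if (!any(occ)) stop("the generating model predicts no event in any year")
  if (any(!occ))
    warning(sprintf("dropping %d year(s) with no predicted event", sum(!occ)))
  years <- years[occ]
  doy <- true_doy[occ]
  noisy <- with_rng_seed(rng_seed,
    doy + round(rnorm(length(doy), 0, truth$observation_noise_sd)))
  if (truth$observation_grid == "every_other_day")
    noisy <- 2 * round((noisy - 1) / 2) + 1   # nearest odd DOY
  noisy <- pmin(pmax(noisy, 1), 366)
  out <- phenology_series(station_id, species, phenophase, years, noisy)
  attr(out, "true_doy") <- doy
  out
}

#' Map latitude to a climate zone of the study gradient
#'
#' Default latitude banding of the eastern monsoon gradient: north
#' tropical below 21.5 N, south subtropical to 25 N, middle
#' subtropical to 31 N, north subtropical to 34 N, warm temperate to
#' 42.5 N, middle temperate above.
#'
#' @param latitude Degrees north; vectorised.
#' @return Character vector of zone labels.
#' @export
zone_from_latitude <- function(latitude) {
  breaks <- c(-Inf, 21.5, 25, 31, 34, 42.5, Inf)
  labels <- c("north_tropical", "south_subtropical", "middle_subtropical",
              "north_subtropical", "warm_temperate", "middle_temperate")
  labels[findInterval(latitude, breaks, rightmost.closed = TRUE)]
}

#' Default TPForc truth parameters for a trigger
#'
#' Realistic generating parameters used by [make_network()]. The
#' temperature trigger (10 degrees C, above the sigmoid midpoint of 8)
#' genuinely truncates forcing accumulation, so the trigger mechanism
#' is operative in the generated data rather than decorative; the
#' photoperiod trigger (12 h) sits well inside the annual daylength
#' range of every study latitude. Sigmoid slope -0.3 per degree C and
#' forcing requirement 20 place events in April-June across the
#' gradient.
#'
#' @param trigger `"temperature"` or `"photoperiod"`.
#' @return A [tpforc_parameters] object.
#' @export
default_truth_parameters <- function(trigger = c("temperature", "photoperiod")) {
  trigger <- match.arg(trigger)
  if (trigger == "temperature") {
    tpforc_parameters("temperature", T_start = 10, f_a = -0.3, f_b = 8,
                      F_star = 20)
  } else {
    tpforc_parameters("photoperiod", P_start = 12, f_a = -0.3, f_b = 10,
                      F_star = 20)
  }
}

#' Generate a synthetic station network with a latitude gradient
#'
#' Emulates a monsoon-gradient observation network: `n_stations`
#' stations evenly spaced across `latitude_range`, with annual mean
#' temperature decreasing (default 0.7 degrees C per degree latitude
#' from 22 degrees C at the southern end) and seasonal amplitude
#' increasing northward (default 8 + 0.35 per degree, reflecting the
#' stronger continentality of the northern monsoon region). The
#' generating bud-growth trigger is assigned by a latitude rule:
#' photoperiod south of `trigger_cutoff_lat`, temperature north of it,
#' creating a testable north-south gradient in trigger frequencies.
#'
#' @param n_stations Number of stations (>= 1).
#' @param latitude_range `c(south, north)` latitude limits, degrees.
#' @param years Phenology years to simulate.
#' @param trigger_cutoff_lat Latitude of the trigger switch.
#' @param observation_noise_sd Observation noise SD, days.
#' @param observation_grid Observation grid (see [synthetic_truth()]).
#' @param rng_seed Base seed; station i uses `rng_seed + i` for weather
#'   and `rng_seed + 10000 + i` for observation noise.
#' @param mean_south Annual mean at the southern end, degrees C.
#' @param mean_lapse Decrease of the annual mean per degree latitude.
#' @param amp_south Seasonal amplitude at the southern end, degrees C.
#' @param amp_gradient Amplitude increase per degree latitude.
#' @return A list with `stations` (a [station_table] with a `latitude`
#'   column), `temperatures` (list of [daily_temperature_series]),
#'   `phenology` (list of [phenology_series]), `truths` (list of
#'   [synthetic_truth()]).
#' @export
make_network <- function(n_stations = 20L,
                         latitude_range = c(18.2, 53.6),
                         years = 1981:2014,
                         trigger_cutoff_lat = 33,
                         observation_noise_sd = 1,
                         observation_grid = "daily",
                         rng_seed = 1L,
                         mean_south = 22, mean_lapse = 0.7,
                         amp_south = 8, amp_gradient = 0.35) {
  stopifnot(n_stations >= 1)
  lats <- if (n_stations == 1L) mean(latitude_range) else
    seq(latitude_range[1L], latitude_range[2L], length.out = n_stations)
  ids <- sprintf("SYN%03d", seq_len(n_stations))
  stations <- station_table(ids, lats,
                            longitude = 110 + (lats - latitude_range[1L]) * 0.5,
                            elevation = 100,
                            climate_zone = zone_from_latitude(lats))
  temperatures <- vector("list", n_stations)
  phenology <- vector("list", n_stations)
  truths <- vector("list", n_stations)
  for (i in seq_len(n_stations)) {
    dlat <- lats[i] - latitude_range[1L]
    wcfg <- weather_gen_config(
      annual_mean = mean_south - mean_lapse * dlat,
      seasonal_amplitude = amp_south + amp_gradient * dlat,
      years = years, rng_seed = rng_seed + i
    )
    temperatures[[i]] <- generate_temperature(wcfg, station_id = ids[i])
    trig <- if (lats[i] < trigger_cutoff_lat) "photoperiod" else "temperature"
    truths[[i]] <- synthetic_truth(default_truth_parameters(trig),
                                   observation_noise_sd = observation_noise_sd,
                                   observation_grid = observation_grid)
    phenology[[i]] <- generate_phenology(
      truths[[i]], temperatures[[i]], lats[i], years,
      rng_seed = rng_seed + 10000L + i, station_id = ids[i]
    )
  }
  names(temperatures) <- names(phenology) <- names(truths) <- ids
  list(stations = stations, temperatures = temperatures,
       phenology = phenology, truths = truths)
}
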