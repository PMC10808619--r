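# Shared fixtures and independent oracles. Oracles are deliberately
# written as plain day-by-day loops / direct formula evaluations,
# independent of the package's vectorised and compiled code paths.

# --- annealer budgets used in tests ----------------------------------------
fast_sa <- function(seed) sa_config_fast(rng_seed = seed)
tiny_sa <- function(seed) sa_config(iterations_per_stage = 40L, n_stages = 20L,
                                    n_restarts = 1L, rng_seed = seed)

# --- fixture builders -------------------------------------------------------

# Constant-temperature series covering Jan 1 (year0 - 1) .. Dec 31 (year1).
const_temp_series <- function(value, year0, year1 = year0,
                              station_id = "CONST") {
  start <- as.Date(sprintf("%d-01-01", year0 - 1L))
  n <- as.integer(as.Date(sprintf("%d-12-31", year1)) - start) + 1L
  daily_temperature_series(station_id, start, rep(value, n))
}

# Deterministic sinusoidal series (no noise) with given mean/amplitude.
sinus_temp_series <- function(annual_mean, amplitude, year0, year1,
                              station_id = "SINUS") {
  cfg <- weather_gen_config(annual_mean = annual_mean,
                            seasonal_amplitude = amplitude,
                            noise_sd = 0, years = year0:year1, rng_seed = 1)
  generate_temperature(cfg, station_id = station_id)
}

# One synthetic station with a known TPForc truth, emulating the study
# gradient (annual mean and seasonal amplitude tied to latitude).
make_truth_station <- function(trigger, seed, years = 1985:2014,
                               noise_sd = 1) {
  lat <- if (trigger == "photoperiod") 25 else 45
  wcfg <- weather_gen_config(
    annual_mean = 22 - 0.7 * (lat - 18.2),
    seasonal_amplitude = 8 + 0.35 * (lat - 18.2),
    years = years, rng_seed = seed
  )
  temps <- generate_temperature(wcfg)
  truth <- synthetic_truth(default_truth_parameters(trigger),
                           observation_noise_sd = noise_sd)
  obs <- generate_phenology(truth, temps, lat, years,
                            rng_seed = seed + 5000L)
  list(latitude = lat, temps = temps, truth = truth, obs = obs)
}

# --- independent oracles ----------------------------------------------------

# Temperature on a given date by direct index arithmetic.
oracle_temp_at <- function(temps, date) {
  temps$values[as.integer(as.Date(date) - temps$start_date) + 1L]
}

# Day-by-day forward model: scalar loop, own sigmoid, own start search.
# pars: list with fields matching the family's parameters.
oracle_predict_doy <- function(family, pars, temps, latitude, year,
                               p = 0.8333) {
  sig <- function(T) 1 / (1 + exp(pars$f_a * (T - pars$f_b)))
  from <- as.Date(sprintf("%d-12-01", year - 1L))
  to <- as.Date(sprintf("%d-12-31", year))
  days <- seq(from, to, by = "day")
  start <- NULL
  if (family == "tpforc_t") {
    d <- as.Date(sprintf("%d-01-21", year))
    while (d <= to) {
      if (oracle_temp_at(temps, d) > pars$T_start) { start <- d; break }
      d <- d + 1L
    }
  } else if (family == "tpforc_p") {
    d <- as.Date(sprintf("%d-01-01", year - 1L)) + 354L + 1L
    while (d <= to) {
      dl <- daylength(latitude, as.integer(format(d, "%j")), p = p)
      if (dl > pars$P_start) { start <- d; break }
      d <- d + 1L
    }
  } else {
    start <- as.Date(sprintf("%d-01-01", year))
  }
  if (is.null(start)) return(NA_real_)
  cum <- 0
  d <- start
  while (d <= to) {
    T <- oracle_temp_at(temps, d)
    dl <- daylength(latitude, as.integer(format(d, "%j")), p = p)
    r <- switch(family,
                tpforc_t = sig(T), tpforc_p = sig(T), uniforc = sig(T),
                photothermal = (dl / 24) * sig(T),
                m1 = (dl / 10) * max(T - pars$T_base, 0))
    cum <- cum + r
    if (cum >= pars$F_star)
      return(as.numeric(d - as.Date(sprintf("%d-01-01", year))) + 1)
    d <- d + 1L
  }
  NA_real_
}

# Independent daylength from a different declination approximation
# (cosine day-angle form), geometric sunrise/sunset (p = 0).
oracle_daylength_p0 <- function(latitude, doy) {
  decl <- -23.44 * pi / 180 * cos(2 * pi * (doy + 10) / 365.25)
  lat <- latitude * pi / 180
  a <- pmin(1, pmax(-1, -tan(lat) * tan(decl)))
  (24 / pi) * acos(a)
}

# Random valid parameter object for a family (used in property tests).
random_parameters <- function(family) {
  F_star <- runif(1, 5, 40)
  switch(family,
         tpforc_t = tpforc_parameters("temperature",
                                      T_start = runif(1, -2, 12),
                                      f_a = runif(1, -1, -0.1),
                                      f_b = runif(1, 4, 16), F_star = F_star),
         tpforc_p = tpforc_parameters("photoperiod",
                                      P_start = runif(1, 10, 14),
                                      f_a = runif(1, -1, -0.1),
                                      f_b = runif(1, 4, 16), F_star = F_star),
         uniforc = comparison_parameters("uniforc", f_a = runif(1, -1, -0.1),
                                         f_b = runif(1, 4, 16),
                                         F_star = F_star),
         photothermal = comparison_parameters("photothermal",
                                              f_a = runif(1, -1, -0.1),
                                              f_b = runif(1, 4, 16),
                                              F_star = F_star),
         m1 = comparison_parameters("m1", T_base = runif(1, -2, 8),
                                    F_star = runif(1, 50, 400)))
}

with_seed_pars <- function(family, seed) {
  set.seed(seed)
  random_parameters(family)
}

# Shift every daily temperature by a constant.
warm_series <- function(temps, delta) {
  daily_temperature_series(temps$station_id, temps$start_date,
                           temps$values + delta)
}
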