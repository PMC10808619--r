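test_that("sigmoid growth rate has the right midpoint, asymptotes and quantiles", {
  expect_equal(bud_growth_rate(10, -0.5, 10), 0.5)
  expect_equal(bud_growth_rate(1e6, -0.5, 10), 1.0)
  expect_equal(bud_growth_rate(-1e6, -0.5, 10), 0.0)
  # solving 1/(1+exp(-0.5 x)) = 0.75 gives x = 2 ln 3
  expect_equal(bud_growth_rate(10 + 2 * log(3), -0.5, 10), 0.75,
               tolerance = 1e-12)
  # strictly increasing in T for f_a < 0
  expect_true(all(diff(bud_growth_rate(seq(-10, 30, 0.5), -0.3, 8)) > 0))
})

test_that("parameter constructors enforce sign and exclusivity constraints", {
  expect_error(tpforc_parameters("temperature", T_start = 5, P_start = 12,
                                 f_a = -0.3, f_b = 10, F_star = 20), "P_start")
  expect_error(tpforc_parameters("temperature", T_start = 5, f_a = 0.3,
                                 f_b = 10, F_star = 20), "f_a")
  expect_error(tpforc_parameters("photoperiod", P_start = 12, f_a = -0.3,
                                 f_b = -1, F_star = 20), "f_b")
  expect_error(comparison_parameters("uniforc", f_a = -0.3, f_b = 10,
                                     F_star = 0), "F_star")
  expect_error(comparison_parameters("m1", F_star = 100), "T_base")
  expect_equal(n_model_parameters("tpforc_t"), 4L)
  expect_equal(n_model_parameters("uniforc"), 3L)
  expect_equal(n_model_parameters("photothermal"), 3L)
  expect_equal(n_model_parameters("m1"), 2L)
})

test_that("parameters round trip through JSON", {
  for (fam in model_families()) {
    pars <- with_seed_pars(fam, 7)
    back <- parameters_from_json(parameters_to_json(pars))
    expect_equal(back, pars)
  }
})

test_that("temperature start date is the first post-Jan-20 threshold crossing", {
  temps <- const_temp_series(10, 2000)
  expect_equal(find_start_date_temperature(temps, 5, 2000),
               as.Date("2000-01-21"))
  expect_true(is.na(find_start_date_temperature(temps, 15, 2000)))
  # ramp crossing the threshold on a known day matches a linear scan
  ramp <- const_temp_series(0, 2000)
  dates <- seq(ramp$start_date, by = "day", length.out = length(ramp$values))
  doy2000 <- as.numeric(dates - as.Date("2000-01-01")) + 1
  ramp$values <- pmax(doy2000, 0) * 0.2   # crosses 8 deg at DOY 41
  got <- find_start_date_temperature(ramp, 8, 2000)
  scan <- dates[dates >= as.Date("2000-01-21")]
  scan <- scan[vapply(scan, function(d) oracle_temp_at(ramp, d) > 8,
                      logical(1))][1]
  expect_equal(got, scan)
  expect_equal(as.integer(format(got, "%j")), 41L)
})

test_that("photoperiod start date is the first post-solstice daylength crossing", {
  # threshold below the solstice daylength: the first searched day
  # (the day after DOY 355, Dec 22 in a non-leap previous year) qualifies
  expect_equal(find_start_date_photoperiod(30, 6, 2002),
               as.Date("2001-12-22"))
  # leap previous year: DOY 355 falls on Dec 20, search starts Dec 21
  expect_equal(find_start_date_photoperiod(30, 6, 2001),
               as.Date("2000-12-21"))
  expect_true(is.na(find_start_date_photoperiod(40, 20, 2001)))
  # 12 h threshold at 40 N: matches a brute scan, near the spring equinox
  got <- find_start_date_photoperiod(40, 12, 2001)
  days <- seq(as.Date("2000-12-21"), as.Date("2001-12-31"), by = "day")
  scan <- days[vapply(days, function(d)
    daylength(40, as.integer(format(d, "%j"))) > 12, logical(1))][1]
  expect_equal(got, scan)
  expect_true(abs(as.integer(format(got, "%j")) - 80) < 10)
  # start date does not depend on temperature at all (no temps argument)
  # and the temperature start date does not depend on latitude (ditto)
  expect_named(formals(find_start_date_photoperiod),
               c("latitude", "P_start", "year", "p"))
  expect_named(formals(find_start_date_temperature),
               c("temps", "T_start", "year"))
})

test_that("forcing accumulation matches closed forms and includes the start day", {
  # constant temperature: rate r per day, F* = 10 r reached on day 10
  temps <- const_temp_series(10, 2000)
  r <- bud_growth_rate(10, -0.3, 8)
  pars <- tpforc_parameters("temperature", T_start = 5, f_a = -0.3, f_b = 8,
                            F_star = 10 * r)
  traj <- accumulate_forcing(temps, pars, 40, 2000)
  expect_equal(traj$predicted_date, traj$start_date + 9)
  expect_equal(traj$cumulative, cumsum(rep(r, 10)), tolerance = 1e-12)
  # F* at most the first day's rate: event on the start date itself
  pars2 <- tpforc_parameters("temperature", T_start = 5, f_a = -0.3, f_b = 8,
                             F_star = r / 2)
  expect_equal(accumulate_forcing(temps, pars2, 40, 2000)$predicted_date,
               accumulate_forcing(temps, pars2, 40, 2000)$start_date)
  # cumulative trajectory is non-decreasing
  expect_true(all(diff(traj$cumulative) >= 0))
})

test_that("compiled predictions equal the R trajectory and the brute-force loop", {
  set.seed(101)
  temps <- generate_temperature(weather_gen_config(annual_mean = 12,
                                                   seasonal_amplitude = 12,
                                                   years = 2000:2004,
                                                   rng_seed = 33))
  for (rep in 1:25) {
    fam <- sample(model_families(), 1)
    pars <- random_parameters(fam)
    lat <- runif(1, 20, 55)
    year <- sample(2000:2004, 1)
    fast <- predict_series(pars, temps, lat, year)
    brute <- oracle_predict_doy(fam, pars, temps, lat, year)
    expect_equal(unname(fast), brute, tolerance = 1e-9)
    if (fam %in% c("tpforc_t", "tpforc_p")) {
      traj <- accumulate_forcing(temps, pars, lat, year)
      expect_equal(unname(fast), traj$predicted_doy, tolerance = 1e-9)
    }
  }
})

test_that("noise-free self-consistency: the generating model reproduces its dates", {
  st <- make_truth_station("photoperiod", seed = 3, noise_sd = 0)
  pred <- predict_series(st$truth$params, st$temps, st$latitude, st$obs$years)
  expect_equal(unname(pred), unname(st$obs$doy))
})

test_that("m1 with T_base above all temperatures never predicts an event", {
  temps <- const_temp_series(10, 2000, 2002)
  pars <- comparison_parameters("m1", T_base = 12, F_star = 10)
  pred <- predict_series(pars, temps, 40, 2000:2002)
  expect_true(all(is.na(pred)))
})

test_that("photothermal is never earlier than uniforc with shared sigmoid", {
  temps <- generate_temperature(weather_gen_config(years = 2000:2003,
                                                   rng_seed = 9))
  for (rep in 1:10) {
    set.seed(200 + rep)
    u <- random_parameters("uniforc")
    ph <- comparison_parameters("photothermal", f_a = u$f_a, f_b = u$f_b,
                                F_star = u$F_star)
    pu <- predict_series(u, temps, 35, 2000:2003)
    pp <- predict_series(ph, temps, 35, 2000:2003)
    ok <- !is.na(pu) & !is.na(pp)
    expect_true(all(pp[ok] >= pu[ok]))
    expect_true(all(!is.na(pu) | is.na(pp)))  # uniforc occurs whenever photothermal does
  }
})

test_that("predicted dates are monotone in F* and in uniform warming", {
  temps <- generate_temperature(weather_gen_config(annual_mean = 10,
                                                   seasonal_amplitude = 13,
                                                   years = 2000:2002,
                                                   rng_seed = 77))
  warmer <- warm_series(temps, 2)
  set.seed(55)
  for (fam in model_families()) {
    for (rep in 1:6) {
      pars <- random_parameters(fam)
      base <- predict_series(pars, temps, 38, 2000:2002)
      # larger forcing requirement: same or later date (NA = never, later)
      pars_hi <- pars; pars_hi$F_star <- pars$F_star * 1.5
      hi <- predict_series(pars_hi, temps, 38, 2000:2002)
      ok <- !is.na(base) & !is.na(hi)
      expect_true(all(hi[ok] >= base[ok]))
      expect_true(all(!is.na(base) | is.na(hi)))
      # uniform warming: same or earlier date
      warm <- predict_series(pars, warmer, 38, 2000:2002)
      ok <- !is.na(base) & !is.na(warm)
      expect_true(all(warm[ok] <= base[ok]))
      expect_true(all(!is.na(warm) | is.na(base)))
    }
  }
})
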