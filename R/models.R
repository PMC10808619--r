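# Forward phenology models: the TPForc family (temperature- or
# photoperiod-triggered bud growth initiation followed by sigmoid forcing
# accumulation) and three classical one-phase comparison models that
# accumulate from January 1st (UniForc, Photothermal, M1).

#' Model family labels
#' @return Character vector of the five supported forward models.
#' @export
model_families <- function() {
  c("tpforc_t", "tpforc_p", "uniforc", "photothermal", "m1")
}

#' Construct TPForc model parameters
#'
#' The TPForc model has four fitted parameters: a bud-growth initiation
#' threshold (`T_start` in degrees C for the temperature trigger,
#' `P_start` in hours for the photoperiod trigger), the sigmoid slope
#' `f_a` (< 0) and midpoint `f_b` (> 0) of the daily growth-rate
#' response to temperature, and the forcing requirement `F_star` (> 0).
#'
#' @param trigger `"temperature"` or `"photoperiod"`.
#' @param T_start Temperature threshold, degrees C (temperature trigger).
#' @param P_start Daylength threshold, hours (photoperiod trigger).
#' @param f_a Sigmoid slope, dimensionless, negative.
#' @param f_b Sigmoid midpoint, degrees C, positive.
#' @param F_star Forcing requirement (accumulated rate units), positive.
#' @return An object of class `tpforc_parameters`.
#' @export
tpforc_parameters <- function(trigger = c("temperature", "photoperiod"),
                              T_start = NULL, P_start = NULL,
                              f_a, f_b, F_star) {
  trigger <- match.arg(trigger)
  if (trigger == "temperature") {
    if (is.null(T_start) || !is.null(P_start))
      stop("temperature trigger requires T_start and no P_start")
  } else {
    if (is.null(P_start) || !is.null(T_start))
      stop("photoperiod trigger requires P_start and no T_start")
  }
  if (f_a >= 0) stop("f_a must be negative")
  if (f_b <= 0) stop("f_b must be positive")
  if (F_star <= 0) stop("F_star must be positive")
  structure(
    list(family = if (trigger == "temperature") "tpforc_t" else "tpforc_p",
         trigger = trigger, T_start = T_start, P_start = P_start,
         f_a = f_a, f_b = f_b, F_star = F_star),
    class = c("tpforc_parameters", "model_parameters")
  )
}

#' Construct comparison-model parameters
#'
#' Three classical one-phase models, all accumulating from January 1st:
#' UniForc (sigmoid temperature response, 3 parameters), Photothermal
#' (sigmoid response weighted by the daylength fraction of the day,
#' 3 parameters), and M1 (growing-degree accumulation above `T_base`
#' scaled by daylength / 10 h, 2 parameters).
#'
#' @param family `"uniforc"`, `"photothermal"` or `"m1"`.
#' @param f_a,f_b Sigmoid slope (< 0) and midpoint (uniforc, photothermal).
#' @param T_base Base temperature, degrees C (m1).
#' @param F_star Forcing requirement, positive.
#' @return An object of class `comparison_parameters`.
#' @export
comparison_parameters <- function(family = c("uniforc", "photothermal", "m1"),
                                  f_a = NULL, f_b = NULL, T_base = NULL,
                                  F_star) {
  family <- match.arg(family)
  if (family %in% c("uniforc", "photothermal")) {
    if (is.null(f_a) || is.null(f_b)) stop(family, " requires f_a and f_b")
    if (f_a >= 0) stop("f_a must be negative")
  } else if (is.null(T_base)) {
    stop("m1 requires T_base")
  }
  if (F_star <= 0) stop("F_star must be positive")
  structure(
    list(family = family, f_a = f_a, f_b = f_b, T_base = T_base,
         F_star = F_star),
    class = c("comparison_parameters", "model_parameters")
  )
}

#' Number of fitted parameters of a model family
#'
#' TPForc sub-models fit 4 parameters (threshold, f_a, f_b, F_star);
#' UniForc and Photothermal fit 3 (f_a, f_b, F_star); M1 fits 2
#' (T_base, F_star). These counts feed the AICc penalty.
#'
#' @param family A family label from [model_families()], or a
#'   `model_parameters` object.
#' @return Integer parameter count.
#' @export
n_model_parameters <- function(family) {
  if (inherits(family, "model_parameters")) family <- family$family
  switch(family,
         tpforc_t = 4L, tpforc_p = 4L,
         uniforc = 3L, photothermal = 3L, m1 = 2L,
         stop("unknown model family: ", family))
}

#' @export
print.model_parameters <- function(x, ...) {
  vals <- x[!vapply(x, is.null, logical(1))]
  vals <- vals[setdiff(names(vals), c("family", "trigger"))]
  cat(sprintf("<%s parameters> %s\n", x$family,
              paste(sprintf("%s=%.4g", names(vals), unlist(vals)),
                    collapse = ", ")))
  invisible(x)
}

#' Serialize model parameters to JSON (and back)
#'
#' @param params A `model_parameters` object.
#' @param path Optional output path.
#' @return JSON string (or `path` invisibly when written).
#' @export
parameters_to_json <- function(params, path = NULL) {
  obj <- params[!vapply(params, is.null, logical(1))]
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname parameters_to_json
#' @param json JSON string or path to a JSON file.
#' @export
parameters_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  if (obj$family %in% c("tpforc_t", "tpforc_p")) {
    tpforc_parameters(trigger = obj$trigger, T_start = obj$T_start,
                      P_start = obj$P_start, f_a = obj$f_a, f_b = obj$f_b,
                      F_star = obj$F_star)
  } else {
    comparison_parameters(family = obj$family, f_a = obj$f_a, f_b = obj$f_b,
                          T_base = obj$T_base, F_star = obj$F_star)
  }
}

#' Daily bud growth rate as a sigmoid of temperature
#'
#' `R_f(T) = 1 / (1 + exp(f_a * (T - f_b)))`. With `f_a < 0` the rate
#' increases strictly with temperature from 0 to 1, passing through 0.5
#' at `T = f_b`. The exponent is guarded against overflow, saturating
#' at 0 or 1.
#'
#' @param T Daily mean air temperature, degrees C; vectorised.
#' @param f_a Slope parameter, negative.
#' @param f_b Midpoint temperature, degrees C.
#' @return Growth rate in (0, 1).
#' @export
bud_growth_rate <- function(T, f_a, f_b) {
  a <- pmin(pmax(f_a * (T - f_b), -700), 700)
  1 / (1 + exp(a))
}

#' Bud growth start date from the temperature trigger
#'
#' The first day with daily mean temperature strictly above `T_start`
#' after the climatological coldest date of the preceding winter,
#' January 20th of the phenology year (the search starts January 21st).
#'
#' @param temps A [daily_temperature_series].
#' @param T_start Temperature threshold, degrees C.
#' @param year Phenology year.
#' @return A `Date`, or `NA` if the threshold is never exceeded by
#'   December 31st.
#' @export
find_start_date_temperature <- function(temps, T_start, year) {
  from <- as.Date(sprintf("%d-01-21", year))
  to <- as.Date(sprintf("%d-12-31", year))
  v <- temperature_window(temps, from, to)
  i <- which(v > T_start)
  if (length(i) == 0L) return(as.Date(NA))
  from + (i[1L] - 1L)
}

#' Bud growth start date from the photoperiod trigger
#'
#' The first day with daylength strictly above `P_start` after the
#' shortest-daylength date, taken as day-of-year 355 (winter solstice)
#' of the previous year; the search starts the following day.
#'
#' @param latitude Station latitude, degrees north.
#' @param P_start Daylength threshold, hours.
#' @param year Phenology year.
#' @param p Daylength coefficient passed to [daylength()].
#' @return A `Date`, or `NA` if `P_start` exceeds the maximum daylength
#'   reached by December 31st of the phenology year.
#' @export
find_start_date_photoperiod <- function(latitude, P_start, year, p = 0.8333) {
  start <- doy_to_date(year - 1L, 355L) + 1L
  to <- as.Date(sprintf("%d-12-31", year))
  dates <- seq(start, to, by = "day")
  dl <- daylength(latitude, as.integer(format(dates, "%j")), p = p)
  i <- which(dl > P_start)
  if (length(i) == 0L) return(as.Date(NA))
  dates[i[1L]]
}

#' Accumulate forcing for one phenology year (full trajectory)
#'
#' Runs the TPForc forward model for a single year and returns the
#' complete trajectory: the trigger (start) date, the daily sigmoid
#' growth rates, their cumulative sum, and the predicted event date —
#' the first day, counting the start date itself, on which the
#' cumulative bud growth state reaches the forcing requirement
#' `F_star`. Non-occurrence (trigger never fires, or `F_star` unmet by
#' December 31st) is reported as an `NA` date, not an error.
#'
#' @param temps A [daily_temperature_series] covering the trigger date
#'   through December 31st of `year`.
#' @param params A [tpforc_parameters] object.
#' @param latitude Station latitude, degrees north.
#' @param year Phenology year.
#' @param p Daylength coefficient for the photoperiod trigger.
#' @return A list of class `forcing_trajectory` with elements
#'   `start_date`, `dates`, `daily_rates`, `cumulative`,
#'   `predicted_date` (Date or `NA`) and `predicted_doy` (DOY of the
#'   phenology year, or `NA`).
#' @export
accumulate_forcing <- function(temps, params, latitude, year, p = 0.8333) {
  stopifnot(inherits(params, "tpforc_parameters"))
  start <- if (params$trigger == "temperature") {
    find_start_date_temperature(temps, params$T_start, year)
  } else {
    find_start_date_photoperiod(latitude, params$P_start, year, p = p)
  }
  end <- as.Date(sprintf("%d-12-31", year))
  if (is.na(start)) {
    traj <- list(start_date = as.Date(NA), dates = as.Date(character(0)),
                 daily_rates = numeric(0), cumulative = numeric(0),
                 predicted_date = as.Date(NA), predicted_doy = NA_real_)
    class(traj) <- "forcing_trajectory"
    return(traj)
  }
  dates <- seq(start, end, by = "day")
  rates <- bud_growth_rate(temperature_window(temps, start, end),
                           params$f_a, params$f_b)
  cum <- cumsum(rates)
  hit <- which(cum >= params$F_star)
  if (length(hit) > 0L) {
    k <- hit[1L]
    pred <- dates[k]
    dates <- dates[seq_len(k)]
    rates <- rates[seq_len(k)]
    cum <- cum[seq_len(k)]
  } else {
    pred <- as.Date(NA)
  }
  traj <- list(start_date = start, dates = dates, daily_rates = rates,
               cumulative = cum, predicted_date = pred,
               predicted_doy = if (is.na(pred)) NA_real_
                               else as.numeric(date_to_doy(pred, year)))
  class(traj) <- "forcing_trajectory"
  traj
}

#' @export
print.forcing_trajectory <- function(x, ...) {
  if (is.na(x$start_date)) {
    cat("<forcing_trajectory> trigger never fired\n")
  } else {
    cat(sprintf("<forcing_trajectory> start %s, predicted %s (%d days tracked)\n",
                format(x$start_date),
                if (is.na(x$predicted_date)) "never (F* unmet)"
                else format(x$predicted_date),
                length(x$dates)))
  }
  invisible(x)
}

# ---- Fast multi-year prediction --------------------------------------------

# Precompute the per-year day windows (previous-year Dec 1 .. Dec 31 of
# the phenology year) as padded matrices for the C++ kernel. Reused
# across model families and parameter proposals during calibration.
build_forcing_context <- function(temps, latitude, years, p = 0.8333) {
  years <- as.integer(years)
  windows <- lapply(years, function(y) {
    from <- as.Date(sprintf("%d-12-01", y - 1L))
    to <- as.Date(sprintf("%d-12-31", y))
    dates <- seq(from, to, by = "day")
    list(
      temp = temperature_window(temps, from, to),
      dl = daylength(latitude, as.integer(format(dates, "%j")), p = p),
      doy = date_to_doy(dates, y),
      # 1-based indices into the window
      idx_jan21 = as.integer(as.Date(sprintf("%d-01-21", y)) - from) + 1L,
      idx_post_solstice = as.integer(doy_to_date(y - 1L, 355L) + 1L - from) + 1L,
      idx_jan1 = as.integer(as.Date(sprintf("%d-01-01", y)) - from) + 1L
    )
  })
  nd <- vapply(windows, function(w) length(w$temp), integer(1))
  D <- max(nd)
  pad <- function(x, fill) c(x, rep(fill, D - length(x)))
  list(
    years = years,
    latitude = latitude,
    temp = vapply(windows, function(w) pad(w$temp, 0), numeric(D)),
    dl = vapply(windows, function(w) pad(w$dl, 0), numeric(D)),
    doy = vapply(windows, function(w) pad(w$doy, 0L), integer(D)),
    n_days = nd,
    idx_jan21 = vapply(windows, `[[`, integer(1), "idx_jan21"),
    idx_post_solstice = vapply(windows, `[[`, integer(1), "idx_post_solstice"),
    idx_jan1 = vapply(windows, `[[`, integer(1), "idx_jan1")
  )
}

# Map a model_parameters object to the C++ family code and packed
# parameter vector [thresh, f_a, f_b, F_star, T_base].
pack_parameters <- function(params) {
  fam <- match(params$family, model_families())
  num <- function(x) if (is.null(x)) 0 else as.numeric(x)
  list(family = fam,
       par = c(num(params$T_start) + num(params$P_start),
               num(params$f_a), num(params$f_b),
               num(params$F_star), num(params$T_base)))
}

context_start_idx <- function(ctx, family) {
  switch(family,
         tpforc_t = ctx$idx_jan21,
         tpforc_p = ctx$idx_post_solstice,
         ctx$idx_jan1)
}

# Kernel call on a prebuilt context; used by calibration's objective.
predict_from_context <- function(ctx, params) {
  pk <- pack_parameters(params)
  pred <- forc_predict_cpp(ctx$temp, ctx$dl, ctx$doy,
                           context_start_idx(ctx, params$family),
                           ctx$n_days, pk$family, pk$par)
  names(pred) <- ctx$years
  pred
}

#' Predict phenology dates for a run of years
#'
#' Runs a forward model for each requested year and returns the
#' predicted event day-of-year (Jan 1 = 1; a prediction falling in
#' December of the previous year, possible under the photoperiod
#' trigger, yields a value <= 0). TPForc sub-models begin accumulation
#' at their fitted trigger date; comparison models accumulate from
#' January 1st. Years in which the trigger never fires or the forcing
#' requirement is not met by December 31st are returned as `NA`
#' (non-occurrence).
#'
#' @param params A [tpforc_parameters] or [comparison_parameters] object.
#' @param temps A [daily_temperature_series] covering December 1st of
#'   the year before each phenology year through December 31st of it.
#' @param latitude Station latitude, degrees north.
#' @param years Integer vector of phenology years.
#' @param p Daylength coefficient.
#' @return Named numeric vector, year -> predicted DOY (`NA` =
#'   non-occurrence).
#' @export
predict_series <- function(params, temps, latitude, years, p = 0.8333) {
  stopifnot(inherits(params, "model_parameters"))
  ctx <- build_forcing_context(temps, latitude, years, p = p)
  predict_from_context(ctx, params)
}
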