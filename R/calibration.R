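# Parameter estimation by Metropolis simulated annealing minimising RMSE,
# with box bounds, geometric cooling, restarts, and selection of the
# better-fitting TPForc trigger.

#' Default calibration bounds for a model family
#'
#' Closed search intervals per fitted parameter: threshold `T_start` in
#' \[-5, 25\] degrees C or `P_start` in \[6, 20\] h, sigmoid slope `f_a`
#' in \[-2, -0.01\], midpoint `f_b` in \[0.1, 30\] degrees C, forcing
#' requirement `F_star` in \[1, 200\], and (M1) base temperature
#' `T_base` in \[-5, 15\] degrees C.
#'
#' @param family A label from [model_families()].
#' @return Named list of `c(lower, upper)` per parameter, in the order
#'   the annealer searches them.
#' @export
default_bounds <- function(family = model_families()) {
  family <- match.arg(family)
  all <- list(T_start = c(-5, 25), P_start = c(6, 20),
              f_a = c(-2, -0.01), f_b = c(0.1, 30),
              F_star = c(1, 200), T_base = c(-5, 15))
  keep <- switch(family,
                 tpforc_t = c("T_start", "f_a", "f_b", "F_star"),
                 tpforc_p = c("P_start", "f_a", "f_b", "F_star"),
                 uniforc = c("f_a", "f_b", "F_star"),
                 photothermal = c("f_a", "f_b", "F_star"),
                 m1 = c("T_base", "F_star"))
  all[keep]
}

#' Simulated annealing configuration
#'
#' Tuning knobs of the Metropolis annealer. Defaults: initial
#' acceptance temperature 10 (objective units, here days of RMSE),
#' geometric cooling by 0.9 per stage over 60 stages of 200 iterations,
#' 5 independent restarts, Gaussian proposals with standard deviation
#' 0.1 of each bound width, reflected at the bounds.
#'
#' @param initial_temperature Starting Metropolis temperature.
#' @param cooling_factor Per-stage multiplier, in (0, 1).
#' @param iterations_per_stage Proposals per cooling stage.
#' @param n_stages Number of cooling stages.
#' @param n_restarts Independent annealing runs; the best-ever solution
#'   across restarts is returned.
#' @param proposal_scale Proposal SD as a fraction of each bound width.
#' @param rng_seed Integer seed; the full run is reproducible given it.
#' @return A list of class `sa_config`.
#' @export
sa_config <- function(initial_temperature = 10, cooling_factor = 0.9,
                      iterations_per_stage = 200L, n_stages = 60L,
                      n_restarts = 5L, proposal_scale = 0.1,
                      rng_seed = 1L) {
  stopifnot(initial_temperature > 0,
            cooling_factor > 0, cooling_factor < 1,
            iterations_per_stage >= 1, n_stages >= 1, n_restarts >= 1,
            proposal_scale > 0)
  structure(
    list(initial_temperature = initial_temperature,
         cooling_factor = cooling_factor,
         iterations_per_stage = as.integer(iterations_per_stage),
         n_stages = as.integer(n_stages),
         n_restarts = as.integer(n_restarts),
         proposal_scale = proposal_scale,
         rng_seed = as.integer(rng_seed)),
    class = "sa_config"
  )
}

#' A reduced-budget annealing configuration
#'
#' Convenience preset with a smaller search budget (2 restarts, 40
#' stages of 120 iterations) for large batch runs such as
#' cross-validation folds and network-wide fitting, where many fits of
#' a 2-4 parameter model are performed and the full default budget is
#' unnecessary.
#'
#' @inheritParams sa_config
#' @return A list of class `sa_config`.
#' @export
sa_config_fast <- function(rng_seed = 1L) {
  sa_config(iterations_per_stage = 120L, n_stages = 40L, n_restarts = 2L,
            rng_seed = rng_seed)
}

# Evaluate with a private RNG stream, restoring the caller's state.
with_rng_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Reflect a proposal into [lo, hi] (repeated folding handles large steps).
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

#' Minimise an objective by Metropolis simulated annealing
#'
#' Box-constrained global minimisation. Each restart draws a uniform
#' starting point in the bounds, then runs `n_stages` stages of
#' `iterations_per_stage` Gaussian proposals, reflected at the bounds.
#' A proposal with objective increase `delta` is accepted with
#' probability `exp(-delta / temperature)`; the temperature is
#' multiplied by `cooling_factor` after each stage. The proposal SD is
#' annealed with the temperature — `proposal_scale` times the bound
#' width times `sqrt(temperature / initial_temperature)`, floored at 2%
#' of `proposal_scale` — so early stages explore the whole box while
#' late stages resolve the plateaus of day-resolution objectives. The
#' best solution ever visited, across all restarts, is returned. Runs
#' are bit-reproducible given `config$rng_seed`, and the caller's RNG
#' state is left untouched.
#'
#' @param objective Function mapping a numeric parameter vector to a
#'   scalar objective value (finite).
#' @param bounds Named list of `c(lower, upper)` per parameter, as from
#'   [default_bounds()].
#' @param config An [sa_config()].
#' @return List with `par` (named numeric vector), `value` (objective
#'   at `par`), `n_evaluations`, and `restart_best` (best value per
#'   restart, a monotone non-increasing cummin gives the trace).
#' @export
simulated_annealing <- function(objective, bounds, config = sa_config()) {
  lo <- vapply(bounds, `[`, numeric(1), 1L)
  hi <- vapply(bounds, `[`, numeric(1), 2L)
  if (any(lo >= hi)) stop("each bound must satisfy lower < upper")
  width <- hi - lo
  d <- length(lo)
  with_rng_seed(config$rng_seed, {
    best_par <- NULL
    best_val <- Inf
    restart_best <- numeric(config$n_restarts)
    n_eval <- 0L
    for (r in seq_len(config$n_restarts)) {
      x <- lo + runif(d) * width
      fx <- objective(x)
      n_eval <- n_eval + 1L
      r_best <- fx
      if (fx < best_val) { best_val <- fx; best_par <- x }
      temp <- config$initial_temperature
      for (stage in seq_len(config$n_stages)) {
        step_sd <- config$proposal_scale * width *
          max(sqrt(temp / config$initial_temperature), 0.02)
        for (it in seq_len(config$iterations_per_stage)) {
          prop <- reflect_into(x + rnorm(d, 0, step_sd), lo, hi)
          fp <- objective(prop)
          n_eval <- n_eval + 1L
          delta <- fp - fx
          if (delta <= 0 || runif(1) < exp(-delta / temp)) {
            x <- prop; fx <- fp
            if (fx < best_val) { best_val <- fx; best_par <- x }
            if (fx < r_best) r_best <- fx
          }
        }
        temp <- temp * config$cooling_factor
      }
      restart_best[r] <- r_best
    }
    names(best_par) <- names(bounds)
    list(par = best_par, value = best_val, n_evaluations = n_eval,
         restart_best = restart_best)
  })
}

# Turn an annealer parameter vector into a model_parameters object.
vector_to_parameters <- function(family, x) {
  switch(family,
         tpforc_t = tpforc_parameters("temperature", T_start = x[["T_start"]],
                                      f_a = x[["f_a"]], f_b = x[["f_b"]],
                                      F_star = x[["F_star"]]),
         tpforc_p = tpforc_parameters("photoperiod", P_start = x[["P_start"]],
                                      f_a = x[["f_a"]], f_b = x[["f_b"]],
                                      F_star = x[["F_star"]]),
         uniforc = comparison_parameters("uniforc", f_a = x[["f_a"]],
                                         f_b = x[["f_b"]],
                                         F_star = x[["F_star"]]),
         photothermal = comparison_parameters("photothermal", f_a = x[["f_a"]],
                                              f_b = x[["f_b"]],
                                              F_star = x[["F_star"]]),
         m1 = comparison_parameters("m1", T_base = x[["T_base"]],
                                    F_star = x[["F_star"]]),
         stop("unknown model family: ", family))
}

#' Penalised residuals between observed and predicted dates
#'
#' Non-occurrence predictions (`NA`) contribute a fixed penalty
#' residual so that the calibration objective stays finite and
#' continuous where the model fails to predict an event.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @param penalty Residual assigned to a non-occurrence, days.
#' @return Numeric residual vector (observed - predicted).
#' @export
penalized_residuals <- function(observed, predicted, penalty = 100) {
  res <- observed - predicted
  res[is.na(predicted)] <- penalty
  res
}

#' RMSE calibration objective for a model on one phenology series
#'
#' Root mean squared error between observed and model-predicted event
#' dates, with non-occurrence years entering as a fixed 100-day
#' residual.
#'
#' @param params A `model_parameters` object.
#' @param observations A [phenology_series].
#' @param temps A [daily_temperature_series].
#' @param latitude Station latitude, degrees north.
#' @param penalty Non-occurrence residual, days.
#' @param p Daylength coefficient.
#' @return RMSE in days.
#' @export
objective_rmse <- function(params, observations, temps, latitude,
                           penalty = 100, p = 0.8333) {
  if (length(observations) == 0L) stop("empty observation series")
  pred <- predict_series(params, temps, latitude, observations$years, p = p)
  sqrt(mean(penalized_residuals(observations$doy, pred, penalty)^2))
}

#' Fit a phenology model to one observation series
#'
#' Calibrates the chosen model family by simulated annealing against
#' the RMSE objective, then evaluates the fit on the fitting data:
#' RMSE, NSE, AICc (with the family's parameter count), and Pearson
#' correlation with its two-sided significance.
#'
#' @param family A label from [model_families()].
#' @param observations A cleaned [phenology_series].
#' @param temps A [daily_temperature_series].
#' @param latitude Station latitude, degrees north.
#' @param bounds Search bounds (default [default_bounds()] for the family).
#' @param config An [sa_config()].
#' @param penalty Non-occurrence residual, days.
#' @param p Daylength coefficient.
#' @return An object of class `fit_result`: `params`, `family`,
#'   `trigger` (TPForc families), `rmse`, `nse`, `aicc`, `pearson_r`,
#'   `pearson_p`, `predictions` (year -> DOY), `n_years`, `k_params`,
#'   `objective_value`, `sa` (annealer bookkeeping).
#' @export
fit_model <- function(family, observations, temps, latitude,
                      bounds = default_bounds(family),
                      config = sa_config(), penalty = 100, p = 0.8333) {
  family <- match.arg(family, model_families())
  k <- n_model_parameters(family)
  n <- length(observations)
  if (n <= k + 2L)
    stop(sprintf("AICc undefined: series has %d years but the %s model needs n > %d",
                 n, family, k + 2L))
  ctx <- build_forcing_context(temps, latitude, observations$years, p = p)
  obs <- observations$doy
  obj <- function(x) {
    names(x) <- names(bounds)
    pred <- predict_from_context(ctx, vector_to_parameters(family, x))
    sqrt(mean(penalized_residuals(obs, pred, penalty)^2))
  }
  sa <- simulated_annealing(obj, bounds, config)
  params <- vector_to_parameters(family, sa$par)
  pred <- predict_from_context(ctx, params)
  res <- penalized_residuals(obs, pred, penalty)
  pred_eff <- obs - res   # predictions with non-occurrence as penalised value
  ct <- pearson_significance(obs, pred_eff)
  out <- structure(
    list(params = params, family = family,
         trigger = if (family %in% c("tpforc_t", "tpforc_p")) params$trigger
                   else NA_character_,
         rmse = rmse_from_residuals(res),
         nse = nse(obs, pred_eff),
         aicc = aicc(obs, pred_eff, k),
         pearson_r = ct$r, pearson_p = ct$p,
         predictions = pred, n_years = n, k_params = k,
         objective_value = sa$value,
         sa = sa[c("n_evaluations", "restart_best")]),
    class = "fit_result"
  )
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: RMSE %.3f d, NSE %.3f, AICc %.2f, r %.3f (p %.3g), n = %d\n",
              x$family, x$rmse, x$nse, x$aicc, x$pearson_r, x$pearson_p,
              x$n_years))
  invisible(x)
}

#' Serialize a fit result to JSON
#' @param fit A `fit_result`.
#' @param path Optional output path.
#' @return JSON string (or `path` invisibly when written).
#' @export
fit_result_json <- function(fit, path = NULL) {
  obj <- list(
    family = fit$family, trigger = fit$trigger,
    params = fit$params[!vapply(fit$params, is.null, logical(1))],
    rmse = fit$rmse, nse = fit$nse, aicc = fit$aicc,
    pearson_r = fit$pearson_r, pearson_p = fit$pearson_p,
    n_years = fit$n_years, k_params = fit$k_params,
    predictions = as.list(fit$predictions)
  )
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Select the better TPForc trigger for a series
#'
#' Chooses between the temperature- and photoperiod-triggered fits of
#' the same series by the lower fitting RMSE; an exact tie goes to the
#' photoperiod variant (fixed, documented tie-break).
#'
#' @param fit_t `fit_result` of the `tpforc_t` model.
#' @param fit_p `fit_result` of the `tpforc_p` model.
#' @return List with `fit` (the chosen `fit_result`) and `trigger`
#'   (`"temperature"` or `"photoperiod"`).
#' @export
select_optimum_tpforc <- function(fit_t, fit_p) {
  stopifnot(fit_t$family == "tpforc_t", fit_p$family == "tpforc_p")
  if (fit_t$rmse < fit_p$rmse) {
    list(fit = fit_t, trigger = "temperature")
  } else {
    list(fit = fit_p, trigger = "photoperiod")
  }
}
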