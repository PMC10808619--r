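# Goodness-of-fit metrics, leave-one-out cross-validation, cross-model
# comparison tables and climate-zone trigger-frequency summaries.

#' Root mean squared error between observed and predicted dates
#'
#' @param observed,predicted Numeric vectors of equal length >= 1.
#' @return RMSE, days.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 1L) stop("empty vectors")
  rmse_from_residuals(observed - predicted)
}

rmse_from_residuals <- function(res) sqrt(mean(res^2))

#' Nash-Sutcliffe Efficiency
#'
#' `NSE = 1 - SSE / sum((O - mean(O))^2)`. NSE of 1 is a perfect fit;
#' 0 means the model does no better than predicting the observed mean
#' every year; negative values are worse than that null model. A
#' zero-variance observed series makes the denominator 0 and the score
#' undefined; `-Inf` is returned as the sentinel rather than an error.
#'
#' @param observed,predicted Numeric vectors of equal length >= 2.
#' @return NSE, dimensionless (<= 1), or `-Inf` when undefined.
#' @export
nse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 2L) stop("NSE needs at least 2 observations")
  denom <- sum((observed - mean(observed))^2)
  sse <- sum((observed - predicted)^2)
  if (denom == 0) {
    if (sse == 0) return(1)
    return(-Inf)
  }
  1 - sse / denom
}

#' Small-sample corrected Akaike Information Criterion
#'
#' `AICc = n * ln(SSE / n) + 2 n (k + 1) / (n - k - 2)`, balancing fit
#' against the number of fitted parameters `k`; smaller is better.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @param k Number of fitted model parameters.
#' @return AICc, dimensionless.
#' @export
aicc <- function(observed, predicted, k) {
  n <- length(observed)
  if (n != length(predicted)) stop("length mismatch")
  if (n <= k + 2) stop(sprintf("AICc undefined for n = %d, k = %d (needs n > k + 2)", n, k))
  sse <- sum((observed - predicted)^2)
  if (sse <= 0) sse <- .Machine$double.xmin  # perfect fit: finite sentinel
  n * log(sse / n) + 2 * n * (k + 1) / (n - k - 2)
}

#' Pearson correlation with two-sided significance
#'
#' @param observed,predicted Numeric vectors of equal length >= 3; both
#'   must have non-zero variance.
#' @return List with `r` (correlation) and `p` (two-sided t-test
#'   p-value); both `NA` when either vector has zero variance.
#' @export
pearson_significance <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 3L) stop("correlation needs at least 3 pairs")
  if (sd(observed) == 0 || sd(predicted) == 0)
    return(list(r = NA_real_, p = NA_real_))
  ct <- cor.test(observed, predicted, method = "pearson",
                 alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Leave-one-out cross-validation of a phenology model
#'
#' For an n-year series, fits the model n times, each time excluding
#' one year, and predicts the held-out year with the parameters fitted
#' to the remaining n - 1 years; every year is held out exactly once.
#' The validation RMSE (VRMSE) is the RMSE between observed dates and
#' the held-out predictions across all n years. Fold f uses annealer
#' seed `config$rng_seed + f` so folds are reproducible but follow
#' independent search trajectories.
#'
#' @inheritParams fit_model
#' @param min_fold_years Minimum calibration-set size per fold; series
#'   shorter than `min_fold_years + 1` are rejected.
#' @return An object of class `cross_validation_result`: `vrmse`,
#'   `per_year_predictions` (year -> held-out predicted DOY),
#'   `n_folds`, `held_out_years`.
#' @export
loocv <- function(family, observations, temps, latitude,
                  bounds = default_bounds(family), config = sa_config(),
                  penalty = 100, p = 0.8333, min_fold_years = 10L) {
  n <- length(observations)
  if (n < min_fold_years + 1L)
    stop(sprintf("series too short for LOOCV: %d years (< %d)",
                 n, min_fold_years + 1L))
  preds <- numeric(n)
  for (f in seq_len(n)) {
    train <- phenology_series(observations$station_id, observations$species,
                              observations$phenophase,
                              observations$years[-f], observations$doy[-f])
    fold_config <- config
    fold_config$rng_seed <- config$rng_seed + f
    fit <- fit_model(family, train, temps, latitude, bounds = bounds,
                     config = fold_config, penalty = penalty, p = p)
    preds[f] <- predict_series(fit$params, temps, latitude,
                               observations$years[f], p = p)
  }
  res <- penalized_residuals(observations$doy, preds, penalty)
  names(preds) <- observations$years
  structure(
    list(vrmse = rmse_from_residuals(res),
         per_year_predictions = preds,
         n_folds = n,
         held_out_years = observations$years),
    class = "cross_validation_result"
  )
}

#' @export
print.cross_validation_result <- function(x, ...) {
  cat(sprintf("<cross_validation_result> %d folds, VRMSE %.3f d\n",
              x$n_folds, x$vrmse))
  invisible(x)
}

#' Compare the TPForc model with the three classical models
#'
#' Fits the TPForc model (both triggers; the lower-RMSE one is
#' selected per series), UniForc, Photothermal and M1 to each series,
#' and aggregates per-family means of RMSE, NSE, Pearson r, the
#' percentage of series with a significant (p < 0.05) positive
#' correlation, AICc, and optionally the LOOCV validation RMSE.
#'
#' @param series_list A [phenology_series] or list of them.
#' @param temps_list A [daily_temperature_series] per series (recycled
#'   if a single one is given).
#' @param latitudes Station latitude per series (recycled).
#' @param bounds_fun Function family -> bounds (default [default_bounds]).
#' @param config An [sa_config()]; series s uses seed
#'   `rng_seed + 1000 * (s - 1)`.
#' @param include_loocv Also run LOOCV per series and family? (slow)
#' @param penalty Non-occurrence residual, days.
#' @param p Daylength coefficient.
#' @return A `data.frame` of class `comparison_table`, one row per
#'   model family (columns `model`, `mean_rmse`, `mean_nse`,
#'   `mean_pearson_r`, `pct_significant`, `mean_aicc`, `mean_vrmse`),
#'   with the per-series fits in attribute `"fits"`.
#' @export
compare_models <- function(series_list, temps_list, latitudes,
                           bounds_fun = default_bounds,
                           config = sa_config(), include_loocv = FALSE,
                           penalty = 100, p = 0.8333) {
  if (inherits(series_list, "phenology_series")) series_list <- list(series_list)
  ns <- length(series_list)
  if (inherits(temps_list, "daily_temperature_series"))
    temps_list <- rep(list(temps_list), ns)
  latitudes <- rep_len(latitudes, ns)
  families <- c("tpforc", "uniforc", "photothermal", "m1")
  new_mat <- function() matrix(NA_real_, ns, length(families),
                               dimnames = list(NULL, families))
  metrics <- list(rmse = new_mat(), nse = new_mat(), r = new_mat(),
                  sig = new_mat(), aicc = new_mat(), vrmse = new_mat())
  fits <- vector("list", ns)
  for (s in seq_len(ns)) {
    cfg <- config
    cfg$rng_seed <- config$rng_seed + 1000L * (s - 1L)
    obs <- series_list[[s]]; tm <- temps_list[[s]]; lat <- latitudes[s]
    fit_t <- fit_model("tpforc_t", obs, tm, lat, bounds_fun("tpforc_t"),
                       cfg, penalty, p)
    cfg$rng_seed <- cfg$rng_seed + 1L
    fit_p <- fit_model("tpforc_p", obs, tm, lat, bounds_fun("tpforc_p"),
                       cfg, penalty, p)
    sel <- select_optimum_tpforc(fit_t, fit_p)
    per_family <- list(tpforc = sel$fit)
    for (fam in c("uniforc", "photothermal", "m1")) {
      cfg$rng_seed <- cfg$rng_seed + 1L
      per_family[[fam]] <- fit_model(fam, obs, tm, lat, bounds_fun(fam),
                                     cfg, penalty, p)
    }
    for (fam in families) {
      ft <- per_family[[fam]]
      metrics$rmse[s, fam] <- ft$rmse
      metrics$nse[s, fam] <- ft$nse
      metrics$r[s, fam] <- ft$pearson_r
      metrics$sig[s, fam] <-
        as.numeric(!is.na(ft$pearson_p) && ft$pearson_p < 0.05 && ft$pearson_r > 0)
      metrics$aicc[s, fam] <- ft$aicc
      if (include_loocv) {
        fam_fit <- if (fam == "tpforc") sel$fit$family else fam
        cfg$rng_seed <- cfg$rng_seed + 100L
        cv <- loocv(fam_fit, obs, tm, lat, bounds_fun(fam_fit), cfg,
                    penalty, p)
        metrics$vrmse[s, fam] <- cv$vrmse
      }
    }
    fits[[s]] <- per_family
  }
  out <- data.frame(
    model = families,
    mean_rmse = colMeans(metrics$rmse),
    mean_nse = colMeans(metrics$nse),
    mean_pearson_r = colMeans(metrics$r),
    pct_significant = 100 * colMeans(metrics$sig),
    mean_aicc = colMeans(metrics$aicc),
    mean_vrmse = colMeans(metrics$vrmse),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("comparison_table", "data.frame")
  attr(out, "fits") <- fits
  out
}

#' Trigger frequencies per climate zone
#'
#' From a table of selected optimum fits labelled with a climate zone
#' and trigger, computes the percentage of photoperiod- and
#' temperature-triggered series per zone (optionally per phenophase),
#' with sample sizes. The two percentages sum to 100 in every cell;
#' cells with n <= `small_n` are flagged as small. Zones appear in
#' north-to-south order ([climate_zones()]); zones with no series are
#' omitted.
#'
#' @param fits A `data.frame` with columns `zone`, `trigger`
#'   (`"temperature"`/`"photoperiod"`) and optionally `phenophase`.
#' @param by_phenophase Split cells by phenophase?
#' @param small_n Flag cells with at most this many series.
#' @return A `data.frame` with columns `zone` (ordered factor),
#'   optionally `phenophase`, `pct_photoperiod`, `pct_temperature`,
#'   `n`, `small`.
#' @export
zone_frequency_summary <- function(fits, by_phenophase = FALSE,
                                   small_n = 5L) {
  stopifnot(all(c("zone", "trigger") %in% names(fits)))
  bad <- !fits$trigger %in% c("temperature", "photoperiod")
  if (any(bad)) stop("trigger must be 'temperature' or 'photoperiod'")
  keys <- if (by_phenophase) list(zone = fits$zone, phenophase = fits$phenophase)
          else list(zone = fits$zone)
  groups <- split(fits, keys, drop = TRUE)
  rows <- lapply(groups, function(g) {
    n <- nrow(g)
    np <- sum(g$trigger == "photoperiod")
    row <- data.frame(zone = as.character(g$zone[1L]),
                      pct_photoperiod = 100 * np / n,
                      pct_temperature = 100 * (n - np) / n,
                      n = n, small = n <= small_n,
                      stringsAsFactors = FALSE)
    if (by_phenophase) row$phenophase <- as.character(g$phenophase[1L])
    row
  })
  out <- do.call(rbind, rows)
  out$zone <- factor(out$zone, levels = climate_zones(), ordered = TRUE)
  out <- out[order(out$zone), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trigger proportions binned by a winter/spring climate metric
#'
#' Bins sites by a climate metric (winter duration in 10-day bins,
#' spring temperature variation in 0.1 degree C bins, or any other
#' width) and reports the proportion of photoperiod- and
#' temperature-triggered optimum models per bin. Bins containing fewer
#' than `min_sites` sites are excluded.
#'
#' @param fits A `data.frame` with columns `trigger` and the metric
#'   named by `metric`.
#' @param metric Column name of the climate metric to bin.
#' @param bin_width Bin width in the metric's units.
#' @param min_sites Bins with fewer sites are dropped.
#' @return A `data.frame` with `bin_lower`, `bin_upper`,
#'   `pct_photoperiod`, `pct_temperature`, `n`.
#' @export
trigger_bin_summary <- function(fits, metric, bin_width,
                                min_sites = 5L) {
  stopifnot(metric %in% names(fits), "trigger" %in% names(fits))
  x <- fits[[metric]]
  lower <- floor(x / bin_width) * bin_width
  groups <- split(fits, lower)
  rows <- lapply(names(groups), function(key) {
    g <- groups[[key]]
    n <- nrow(g)
    if (n < min_sites) return(NULL)
    lo <- as.numeric(key)
    data.frame(bin_lower = lo, bin_upper = lo + bin_width,
               pct_photoperiod = 100 * mean(g$trigger == "photoperiod"),
               pct_temperature = 100 * mean(g$trigger == "temperature"),
               n = n)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(bin_lower = numeric(0), bin_upper = numeric(0),
                      pct_photoperiod = numeric(0),
                      pct_temperature = numeric(0), n = integer(0))
  out[order(out$bin_lower), , drop = FALSE]
}
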