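test_that("the annealer minimises a convex quadratic and respects bounds", {
  obj <- function(x) (x[1] - 2.5)^2 + 1
  res <- simulated_annealing(obj, list(x = c(-10, 10)),
                             sa_config(n_stages = 40, iterations_per_stage = 100,
                                       n_restarts = 2, rng_seed = 1))
  expect_equal(unname(res$par), 2.5, tolerance = 1e-2)
  expect_equal(res$value, obj(res$par), tolerance = 1e-12)

  # multi-dimensional: solution always inside the box
  obj2 <- function(x) sum((x - c(0, 5))^2)
  b <- list(a = c(-1, 1), b = c(0, 3))
  res2 <- simulated_annealing(obj2, b, sa_config(n_stages = 20,
                                                 iterations_per_stage = 50,
                                                 n_restarts = 3, rng_seed = 2))
  expect_true(res2$par[["a"]] >= -1 && res2$par[["a"]] <= 1)
  expect_true(res2$par[["b"]] >= 0 && res2$par[["b"]] <= 3)
  # the boundary optimum b = 3 is found
  expect_equal(unname(res2$par), c(0, 3), tolerance = 5e-2)
})

test_that("the annealer is bit-reproducible and leaves the caller's RNG alone", {
  obj <- function(x) sum(x^2)
  b <- list(u = c(-4, 4), v = c(-4, 4))
  cfg <- sa_config(n_stages = 10, iterations_per_stage = 30, n_restarts = 2,
                   rng_seed = 99)
  r1 <- simulated_annealing(obj, b, cfg)
  set.seed(123); before <- rnorm(3)
  set.seed(123)
  r2 <- simulated_annealing(obj, b, cfg)
  after <- rnorm(3)
  expect_identical(r1$par, r2$par)
  expect_identical(r1$value, r2$value)
  expect_identical(before, after)
})

test_that("proposal reflection folds any point into the bounds", {
  set.seed(8)
  for (i in 1:200) {
    lo <- runif(1, -5, 0); hi <- lo + runif(1, 0.1, 10)
    x <- runif(1, lo - 30, hi + 30)
    y <- budforc:::reflect_into(x, lo, hi)
    expect_true(y >= lo - 1e-12 && y <= hi + 1e-12)
  }
  # points already inside are unchanged
  expect_equal(budforc:::reflect_into(0.3, 0, 1), 0.3)
})

test_that("RMSE objective handles exact fits, residuals and non-occurrence", {
  st <- make_truth_station("temperature", seed = 4, noise_sd = 0,
                           years = 2001:2012)
  # generating parameters on noise-free data: objective is zero
  expect_equal(objective_rmse(st$truth$params, st$obs, st$temps, st$latitude),
               0)
  # residuals [+3, -4] give sqrt((9+16)/2)
  expect_equal(rmse(c(103, 96), c(100, 100)), sqrt(25 / 2))
  expect_equal(rmse(c(103, 96), c(100, 100)), 3.5355, tolerance = 1e-4)
  # a non-occurrence enters as the 100-day penalty residual
  res <- penalized_residuals(c(100, 101, 99, 102), c(100, 101, 99, NA))
  expect_equal(res, c(0, 0, 0, 100))
  expect_equal(sqrt(mean(res^2)), 50)
})

test_that("annealing matches a coarse grid search on a tiny instance", {
  st <- make_truth_station("temperature", seed = 6, noise_sd = 0,
                           years = 2001:2005)
  ctx_obj <- function(x) {
    pars <- tpforc_parameters("temperature", T_start = x[1], f_a = x[2],
                              f_b = x[3], F_star = x[4])
    objective_rmse(pars, st$obs, st$temps, st$latitude)
  }
  # 10^4-point coarse grid over the default bounds
  b <- default_bounds("tpforc_t")
  grid <- expand.grid(T_start = seq(b$T_start[1], b$T_start[2], length.out = 10),
                      f_a = seq(b$f_a[1], b$f_a[2], length.out = 10),
                      f_b = seq(b$f_b[1], b$f_b[2], length.out = 10),
                      F_star = seq(b$F_star[1], b$F_star[2], length.out = 10))
  grid_best <- min(apply(as.matrix(grid), 1, ctx_obj))
  sa <- simulated_annealing(ctx_obj, b, fast_sa(31))
  expect_lte(sa$value, grid_best + 0.25)
})

test_that("fitting noise-free synthetic data recovers the generating dates", {
  # the RMSE objective has integer-day plateaus, so single seeds can
  # settle one day off in a few years; the recovery run is assessed on
  # its mean, with a 1-day cap per seed
  rmses <- vapply(c(11, 12, 13, 15), function(seed) {
    st <- make_truth_station("temperature", seed = seed, noise_sd = 0,
                             years = 1995:2014)
    fit <- fit_model("tpforc_t", st$obs, st$temps, st$latitude,
                     config = sa_config(rng_seed = seed))
    expect_equal(fit$n_years, 20)
    expect_equal(fit$k_params, 4)
    b <- default_bounds("tpforc_t")
    expect_true(fit$params$T_start >= b$T_start[1] &&
                fit$params$T_start <= b$T_start[2])
    expect_true(fit$params$F_star >= b$F_star[1] &&
                fit$params$F_star <= b$F_star[2])
    fit$rmse
  }, numeric(1))
  expect_lte(mean(rmses), 0.5)
  expect_true(all(rmses <= 1))
})

test_that("fit_model rejects series too short for AICc", {
  st <- make_truth_station("temperature", seed = 14, noise_sd = 0,
                           years = 2001:2012)
  short <- phenology_series("X", "sp", "first_leaf_unfolding",
                            st$obs$years[1:6], st$obs$doy[1:6])
  expect_error(fit_model("tpforc_t", short, st$temps, st$latitude,
                         config = tiny_sa(1)), "AICc undefined")
})

test_that("NSE of a constant observed series is the undefined sentinel", {
  expect_identical(nse(c(100, 100, 100), c(99, 100, 101)), -Inf)
  expect_identical(nse(c(100, 100, 100), c(100, 100, 100)), 1)
})

test_that("trigger selection takes the lower RMSE and ties go to photoperiod", {
  mk <- function(family, rmse) structure(list(family = family, rmse = rmse),
                                         class = "fit_result")
  expect_equal(select_optimum_tpforc(mk("tpforc_t", 4), mk("tpforc_p", 5))$trigger,
               "temperature")
  expect_equal(select_optimum_tpforc(mk("tpforc_t", 5), mk("tpforc_p", 4))$trigger,
               "photoperiod")
  expect_equal(select_optimum_tpforc(mk("tpforc_t", 4), mk("tpforc_p", 4))$trigger,
               "photoperiod")
})

test_that("a 34-year fit completes within the performance budget", {
  st <- make_truth_station("photoperiod", seed = 21, years = 1981:2014)
  elapsed <- system.time(
    fit_model("tpforc_p", st$obs, st$temps, st$latitude, config = fast_sa(1))
  )["elapsed"]
  expect_lt(elapsed, 60)
})

test_that("fit results serialise to JSON with parameters and metrics", {
  st <- make_truth_station("temperature", seed = 16, noise_sd = 0,
                           years = 2000:2011)
  fit <- fit_model("tpforc_t", st$obs, st$temps, st$latitude,
                   config = tiny_sa(2))
  js <- jsonlite::fromJSON(fit_result_json(fit))
  expect_equal(js$family, "tpforc_t")
  expect_equal(js$rmse, fit$rmse, tolerance = 1e-12)
  expect_equal(js$n_years, 12)
  expect_length(js$predictions, 12)
})
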