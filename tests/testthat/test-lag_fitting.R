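fast_identifiable_spec <- function(lag = 12) {
  # sink-condition toy (large CL relative to dissolution) so the plasma
  # curve responds sharply to the lag time
  toy_spec(diam_um = 3, lag_h = lag, dose = 20, vd_l = 10, ke = 0.08,
           cl_ml_h = 5000, D = 1.17e-11, name = "fit_toy")
}

test_that("the loss is at solver-noise level at the generating parameters", {
  spec <- fast_identifiable_spec()
  obs <- generate_synthetic_observed(spec, seq(2, 96, by = 2), noise_cv = 0)
  pr <- fit_problem(obs, spec, free = "lag_1", loss = "log", lloq = 1e-9)
  expect_lt(fit_objective(c(lag_1 = 12), pr), 1e-6)
})

test_that("pushing all lags past the horizon leaves only the data's energy", {
  spec <- fast_identifiable_spec()
  obs <- generate_synthetic_observed(spec, seq(2, 96, by = 2), noise_cv = 0)
  pr <- fit_problem(obs, spec, free = "lag_1", loss = "linear",
                    upper = c(lag_1 = 2000))
  expect_equal(fit_objective(c(lag_1 = 1000), pr), sum(obs$conc_ng_ml^2))
})

test_that("loss at the truth under additive noise follows its chi-square
           expectation", {
  spec <- fast_identifiable_spec()
  schedule <- seq(4, 96, by = 1)
  clean <- generate_synthetic_observed(spec, schedule, noise_cv = 0)
  keep <- clean$conc_ng_ml > 50 # keep sigma small relative to the signal
  sigma <- 2
  set.seed(7)
  noisy <- conc_series(clean$time_h[keep],
                       clean$conc_ng_ml[keep] + rnorm(sum(keep), 0, sigma))
  pr <- fit_problem(noisy, spec, free = "lag_1", loss = "linear")
  loss <- fit_objective(c(lag_1 = 12), pr)
  n <- sum(keep)
  expect_lt(abs(loss - n * sigma^2), 3 * sqrt(2 * n) * sigma^2)
})

test_that("a single free lag is recovered and matches a grid search", {
  spec <- fast_identifiable_spec(lag = 12)
  obs <- generate_synthetic_observed(spec, seq(2, 96, by = 2), noise_cv = 0)
  pr <- fit_problem(obs, spec, free = "lag_1", loss = "log", lloq = 1e-9,
                    upper = c(lag_1 = 48), seed = 3)
  fit <- fit_depot(pr, control = list(pop_size = 12, max_gen = 30))
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["lag_1"]] - 12), 0.5)
  # independent oracle: exhaustive search on a 0.25 h grid
  grid <- seq(0, 48, by = 0.25)
  losses <- vapply(grid, function(g) fit_objective(c(lag_1 = g), pr), numeric(1))
  expect_lt(abs(fit$estimates[["lag_1"]] - grid[which.min(losses)]), 0.5)
  expect_lte(fit$objective_value, min(losses) + 1e-8)
  expect_false(fit$weakly_identified[["lag_1"]])
})

test_that("fitting with no free parameters returns the base spec loss", {
  spec <- fast_identifiable_spec()
  obs <- generate_synthetic_observed(spec, seq(4, 96, by = 4), noise_cv = 0.1,
                                     seed = 5)
  pr <- fit_problem(obs, spec, free = character(0))
  fit <- fit_depot(pr)
  expect_true(fit$converged)
  expect_equal(fit$objective_value,
               fit_objective(setNames(numeric(0), character(0)), pr))
})

test_that("fits improve monotonically and are seed-reproducible", {
  spec <- fast_identifiable_spec(lag = 12)
  obs <- generate_synthetic_observed(spec, seq(2, 96, by = 4), noise_cv = 0.05,
                                     seed = 11)
  pr <- fit_problem(obs, spec, free = c("lag_1", "bioavailability"),
                    upper = c(lag_1 = 48, bioavailability = 1), seed = 42)
  fit1 <- fit_depot(pr, control = list(pop_size = 10, max_gen = 15))
  fit2 <- fit_depot(pr, control = list(pop_size = 10, max_gen = 15))
  expect_lte(fit1$objective_value, fit1$initial_objective)
  expect_identical(fit1$estimates, fit2$estimates)
  expect_identical(fit1$objective_value, fit2$objective_value)
})

test_that("under-determined problems are flagged at definition time", {
  spec <- fast_identifiable_spec()
  obs <- generate_synthetic_observed(spec, c(6, 24, 48), noise_cv = 0)
  expect_warning(fit_problem(obs, spec, free = c("lag_1", "bioavailability")),
                 "under-determined")
  expect_error(fit_problem(obs, spec, free = "nonsense"), "unknown free")
})

test_that("noise-free synthetic data returns the generating lags exactly", {
  spec <- example_spec("dog_R")
  truth <- spec$bins$lag_time_h
  obs <- generate_synthetic_observed(spec, dog_schedule(), noise_cv = 0)
  free <- paste0("lag_", 1:12)
  pr <- suppressWarnings(
    fit_problem(obs, spec, free = free, loss = "log", seed = 42,
                upper = setNames(rep(2 * max(obs$time_h), 12), free)))
  fit <- fit_depot(pr, control = list(pop_size = 36, max_gen = 120))
  expect_lt(fit$objective_value, 1e-8)
  expect_lt(max(abs(fit$estimates - truth)), 0.5)
})
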