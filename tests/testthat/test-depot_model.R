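test_that("bin_radius inverts the sphere mass-radius relation", {
  rho <- 1.2
  m_1um <- 4 / 3 * pi * (1e-4)^3 * (rho * 1000) # mg of a 1 um-radius sphere
  expect_equal(bin_radius(m_1um, 1, rho), 1, tolerance = 1e-12)
  expect_equal(bin_radius(0, 1, rho), 0)
  expect_equal(bin_radius(5 * m_1um, 10, rho),
               (5 * m_1um / 10 * 3 / (4 * pi * rho * 1000))^(1 / 3) * 1e4,
               tolerance = 1e-12)
  # halving the mass at fixed count scales r by 2^(-1/3)
  r1 <- bin_radius(m_1um, 4, rho)
  r2 <- bin_radius(m_1um / 2, 4, rho)
  expect_equal(r2 / r1, 2^(-1 / 3), tolerance = 1e-12)
})

test_that("unit conversions used by the model are exact", {
  expect_equal(convert_unit(1.17e-11, "m^2/s", "cm^2/h"), 4.212e-4)
  expect_equal(convert_unit(3, "um", "cm"), 3e-4)
  expect_equal(convert_unit(1.2, "g/cm^3", "mg/mL"), 1200)
  expect_equal(convert_unit(35, "L/h", "mL/h"), 35000)
  expect_error(convert_unit(1, "um", "mg/mL"), "cannot convert")
  expect_error(convert_unit(1, "furlong", "cm"), "unknown unit")
})

test_that("the state is static before the first lag time", {
  spec <- toy_spec(n_bins = 3, diam_um = c(1, 2, 4), lag_h = c(5, 10, 20))
  st <- list(solid_mass = unit_normalize(spec)$solid0,
             regional_dissolved = 0, central_mass = 0, eliminated_mass = 0)
  d <- state_derivative(2, st, spec)
  expect_equal(d$solid_mass, rep(0, 3))
  expect_equal(d$regional_dissolved, 0)
  expect_equal(d$central_mass, 0)
  expect_equal(d$eliminated_mass, 0)
})

test_that("at regional saturation dissolution stops and transfer continues", {
  spec <- toy_spec(lag_h = 0)
  p <- unit_normalize(spec)
  st <- list(solid_mass = p$solid0 / 2,
             regional_dissolved = p$S * p$v_region, # exactly saturated
             central_mass = 1, eliminated_mass = 0)
  d <- state_derivative(10, st, spec)
  expect_equal(d$solid_mass, 0)
  expect_equal(d$regional_dissolved, -p$S * p$cl_perf)
  expect_equal(d$central_mass, p$S * p$cl_perf - 1 * p$ke)
})

test_that("derivative components sum to zero (closed mass balance)", {
  for (i in 1:10) {
    spec <- random_depot_spec(i)
    p <- unit_normalize(spec)
    set.seed(i)
    st <- list(solid_mass = p$solid0 * runif(p$n_bins),
               regional_dissolved = runif(1, 0, p$S * p$v_region),
               central_mass = runif(1, 0, p$amount),
               eliminated_mass = 0)
    d <- state_derivative(max(p$lag) + 1, st, spec)
    total <- sum(d$solid_mass) + d$regional_dissolved + d$central_mass +
      d$eliminated_mass
    scale <- max(abs(c(d$solid_mass, d$regional_dissolved, d$central_mass)))
    expect_lt(abs(total), 1e-12 * max(scale, 1))
  }
})

test_that("compiled and reference derivatives agree", {
  spec <- random_depot_spec(99)
  p <- unit_normalize(spec)
  y <- c(p$solid0 * 0.7, 0.3 * p$S * p$v_region, 0.1 * p$amount, 0.01)
  r_ref <- laidepot:::.depot_rhs(max(p$lag) + 1, y, p)[[1]]
  sim <- simulate_depot(spec, max(p$lag) + 1) # exercises the compiled path
  expect_s3_class(sim, "depot_sim")
  d <- state_derivative(max(p$lag) + 1, list(
    solid_mass = y[seq_len(p$n_bins)], regional_dissolved = y[p$n_bins + 1],
    central_mass = y[p$n_bins + 2], eliminated_mass = y[p$n_bins + 3]), spec)
  expect_equal(c(d$solid_mass, d$regional_dissolved, d$central_mass,
                 d$eliminated_mass), r_ref, tolerance = 1e-12)
})

test_that("zero dose gives an identically zero plasma curve", {
  spec <- toy_spec(dose = 0)
  sim <- simulate_depot(spec, 48)
  expect_true(all(sim$plasma$conc_ng_ml == 0))
  expect_true(all(sim$solids == 0))
})

test_that("instantaneous dissolution reproduces the two-rate closed form", {
  # one bin, no lag, D scaled up so dissolution is ~1e5 x faster than
  # transfer and effectively immediate; S is large enough that the regional
  # pool never saturates. The model then
  # collapses to first-order transfer k_a = CL_perf / V_region into a
  # one-compartment model with elimination ke.
  dose <- 10
  vd_l <- 10
  ke <- 0.1
  v_region <- 0.5
  cl_ml_h <- 0.5 # k_a = 1 per hour
  spec <- toy_spec(diam_um = 1, lag_h = 0, dose = dose, vd_l = vd_l, ke = ke,
                   cl_ml_h = cl_ml_h, S = 100, D = 4.69e-12 * 10,
                   v_region = v_region)
  ka <- cl_ml_h / v_region
  tt <- seq(0.5, 48, by = 0.5)
  sim <- simulate_depot(spec, 48, output_times = tt)
  closed <- dose * ka / (vd_l * (ka - ke)) * (exp(-ke * tt) - exp(-ka * tt)) *
    1000 # mg/L -> ng/mL
  got <- sim$plasma$conc_ng_ml[match(tt, sim$plasma$time_h)]
  expect_equal(got, closed, tolerance = 0.005)
})

test_that("total mass is conserved along every trajectory", {
  for (i in 1:8) {
    spec <- random_depot_spec(i)
    p <- unit_normalize(spec)
    sim <- simulate_depot(spec, max(p$lag) + 200)
    expect_lt(max(abs(mass_at(sim) - p$amount)) / p$amount, 1e-6)
  }
})

test_that("complete AUC obeys the transit identity F*dose/(Vd*ke)", {
  for (i in 1:6) {
    spec <- random_depot_spec(i + 50)
    d <- spec$disposition
    sim <- simulate_to_completion(spec)
    auc <- auc_trapz(sim$plasma$time_h, sim$plasma$conc_ng_ml)
    expected <- d$bioavailability * spec$dose_mg /
      (d$vd_l * d$ke_per_h) * 1000 # mg*h/L -> ng*h/mL
    expect_equal(auc, expected, tolerance = 0.01)
  }
})

test_that("doubling every particle diameter never increases Cmax", {
  for (i in 1:6) {
    spec <- random_depot_spec(i + 70)
    spec2 <- depot_model_spec(
      physchem = spec$physchem, disposition = spec$disposition,
      bins = size_bin_set(spec$bins$mass_fraction,
                          spec$bins$mean_diameter_um * 2,
                          lag_time_h = spec$bins$lag_time_h),
      dose_mg = spec$dose_mg, depot_volume_ml = spec$depot_volume_ml)
    t_end <- max(spec$bins$lag_time_h) + 300
    c1 <- max(simulate_depot(spec, t_end)$plasma$conc_ng_ml)
    c2 <- max(simulate_depot(spec2, t_end)$plasma$conc_ng_ml)
    expect_lte(c2, c1 * (1 + 1e-9))
  }
})

test_that("plasma is zero up to the smallest lag and solids stay in range", {
  for (i in 1:6) {
    spec <- random_depot_spec(i + 30)
    p <- unit_normalize(spec)
    sim <- simulate_depot(spec, max(p$lag) + 150)
    pre <- sim$plasma$time_h <= min(p$lag)
    expect_true(all(sim$plasma$conc_ng_ml[pre] == 0))
    expect_true(all(sim$solids >= 0))
    # solids never increase (regional concentration stays below S here)
    expect_true(all(apply(sim$solids, 2, function(s) all(diff(s) <= 1e-9))))
  }
})

test_that("simulation output grids behave", {
  spec <- toy_spec(lag_h = 2)
  sim <- simulate_depot(spec, 10, output_times = c(1, 2, 5, 10))
  expect_equal(sim$plasma$time_h, c(0, 1, 2, 5, 10)) # origin prepended
  expect_error(simulate_depot(spec, 10, output_times = c(5, 20)), "exceed")
  expect_error(simulate_depot(spec, -1), "positive")
})
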