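test_that("default cutpoints partition unit mass into the standard 12 bins", {
  cuts <- default_cut_fractions()
  expect_length(cuts, 13)
  expect_equal(diff(cuts),
               c(0.02, 0.03, 0.05, rep(0.10, 9)))
  expect_equal(sum(diff(cuts)), 1.0)
})

test_that("psd constructor enforces its invariants", {
  expect_s3_class(particle_size_distribution(c(1, 2, 3), c(0.2, 0.7, 1)), "psd")
  expect_error(particle_size_distribution(c(1), c(1)), "at least 2")
  expect_error(particle_size_distribution(c(2, 1), c(0.5, 1)), "increasing")
  expect_error(particle_size_distribution(c(1, 2), c(0.8, 0.5)), "non-decreasing")
  expect_error(particle_size_distribution(c(1, 2), c(0.5, 0.9)), "equal 1")
  expect_error(particle_size_distribution(c(-1, 2), c(0.5, 1)), "positive")
})

test_that("a monodisperse step distribution gives every bin the same diameter", {
  psd <- particle_size_distribution(c(5 - 1e-9, 5), c(0, 1))
  bins <- bin_psd(psd)
  expect_equal(nrow(bins), 12)
  expect_equal(bins$mean_diameter_um, rep(5, 12), tolerance = 1e-8)
  expect_equal(sum(bins$mass_fraction), 1)
})

test_that("two-point psd matches a numerical quadrature of the interpolant", {
  psd <- particle_size_distribution(c(1, 2), c(0.5, 1))
  bins <- bin_psd(psd, cuts = c(0, 0.5, 1))
  # independent oracle: integrate the piecewise-linear quantile function
  # (all mass below 1 um maps to d = 1; above, d rises linearly to 2)
  quantile_fun <- function(q) ifelse(q <= 0.5, 1, 1 + (q - 0.5) / 0.5)
  oracle <- c(
    stats::integrate(quantile_fun, 0, 0.5)$value / 0.5,
    stats::integrate(quantile_fun, 0.5, 1)$value / 0.5)
  expect_equal(bins$mean_diameter_um, oracle, tolerance = 1e-6)
  expect_equal(oracle, c(1, 1.5), tolerance = 1e-6)
})

test_that("lognormal psd bin means match the truncated-lognormal closed form", {
  mu <- log(0.9)
  sigma <- 0.8
  q <- seq(0.002, 0.998, length.out = 100)
  psd_d <- exp(mu + sigma * qnorm(q))
  cum <- q
  cum[length(cum)] <- 1
  psd <- particle_size_distribution(psd_d, cum)
  bins <- bin_psd(psd)
  cuts <- default_cut_fractions()
  # closed form for E[X | a < F(X) < b] of a lognormal in its own
  # mass-quantile coordinates
  lo <- head(cuts, -1)
  hi <- tail(cuts, -1)
  oracle <- exp(mu + sigma^2 / 2) *
    (pnorm(qnorm(hi) - sigma) - pnorm(qnorm(lo) - sigma)) / (hi - lo)
  expect_equal(bins$mean_diameter_um, oracle, tolerance = 0.01)
})

test_that("bin mean diameters are non-decreasing for random monotone psds", {
  for (i in 1:10) {
    set.seed(200 + i)
    n <- sample(20:80, 1)
    d <- sort(exp(rnorm(n, 0, 1)))
    cum <- sort(runif(n))
    cum <- (cum - cum[1]) / (cum[n] - cum[1])
    keep <- c(TRUE, diff(d) > 1e-9)
    psd <- particle_size_distribution(d[keep], cum[keep])
    bins <- bin_psd(psd)
    expect_true(all(diff(bins$mean_diameter_um) >= -1e-12))
  }
})

test_that("bin means are stable under psd grid refinement", {
  mu <- log(1.2)
  sigma <- 0.7
  make <- function(n) {
    q <- seq(0.002, 0.998, length.out = n)
    cum <- q
    cum[n] <- 1
    particle_size_distribution(exp(mu + sigma * qnorm(q)), cum)
  }
  b100 <- bin_psd(make(100))
  b1000 <- bin_psd(make(1000))
  expect_equal(b100$mean_diameter_um, b1000$mean_diameter_um, tolerance = 0.01)
})

test_that("particle counts follow the sphere-mass allocation rule", {
  rho <- 1.2
  d_um <- 2
  one_sphere_mg <- (pi / 6) * (rho * 1000) * (d_um * 1e-4)^3
  bins <- size_bin_set(1, d_um, lag_time_h = 0)
  got <- assign_particle_counts(bins, dose_mg = one_sphere_mg,
                                bioavailability = 1, density_g_cm3 = rho)
  expect_equal(got$particle_count, 1, tolerance = 1e-12)

  # linearity in dose
  b2 <- size_bin_set(c(0.3, 0.7), c(1, 4), lag_time_h = 0)
  n1 <- assign_particle_counts(b2, 10, 1, rho)$particle_count
  n2 <- assign_particle_counts(b2, 20, 1, rho)$particle_count
  expect_equal(n2, 2 * n1)

  # hand unit conversion for a fine 2% bin: 1 mg of 0.584 um spheres
  bR <- size_bin_set(c(0.02, 0.98), c(0.584, 5), lag_time_h = 0)
  got <- assign_particle_counts(bR, 50, 1, 1.2)
  mass_bin1_mg <- 0.02 * 50
  sphere_cm3 <- (pi / 6) * (0.584e-4)^3
  sphere_mg <- sphere_cm3 * 1.2 * 1000
  expect_equal(got$particle_count[1], mass_bin1_mg / sphere_mg,
               tolerance = 1e-12)
  # initial solid mass is conserved exactly
  expect_equal(sum(attr(got, "solid0_mg")), 1 * 50)
  gotF <- assign_particle_counts(bR, 50, 0.83, 1.2)
  expect_equal(sum(attr(gotF, "solid0_mg")), 0.83 * 50)
})

test_that("bin csv round-trips", {
  bins <- size_bin_set(c(0.25, 0.75), c(1.5, 3), lag_time_h = c(2, 4))
  bins <- assign_particle_counts(bins, 10, 1, 1.2)
  path <- tempfile(fileext = ".csv")
  write_bins_csv(bins, path)
  back <- read_bins_csv(path)
  expect_equal(back$mass_fraction, bins$mass_fraction)
  expect_equal(back$mean_diameter_um, bins$mean_diameter_um)
  expect_equal(back$lag_time_h, bins$lag_time_h)
  expect_equal(back$particle_count, bins$particle_count, tolerance = 1e-12)
})
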