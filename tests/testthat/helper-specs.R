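# shared builders for test model specifications (constructed in code, no
# stored fixtures beyond the packaged YAML specs)

toy_spec <- function(n_bins = 1, diam_um = 2, lag_h = 0, dose = 10, F = 1,
                     vd_l = 10, ke = 0.1, cl_ml_h = 500, S = 0.00704,
                     D = 4.69e-12, layer_um = 3, rho = 1.2, v_region = 0.5,
                     name = "toy") {
  diam <- rep_len(diam_um, n_bins)
  frac <- rep(1 / n_bins, n_bins)
  depot_model_spec(
    physchem = phys_chem_params(S, rho, D, layer_um),
    disposition = disposition_params(vd_l, ke, cl_ml_h, F),
    bins = size_bin_set(frac, sort(diam), lag_time_h = rep_len(lag_h, n_bins)),
    dose_mg = dose, depot_volume_ml = v_region, name = name)
}

# reproducible random-but-valid spec; parameters span the regimes of
# interest (both dissolution-limited and transfer-limited) while keeping
# complete release fast enough to test the AUC transit identity
random_depot_spec <- function(i) {
  set.seed(1000 + i)
  n <- sample(2:4, 1)
  diam <- sort(exp(runif(n, log(0.5), log(12))))
  frac <- runif(n, 0.2, 1)
  frac <- frac / sum(frac)
  lag <- sort(runif(n, 0, 48))
  depot_model_spec(
    physchem = phys_chem_params(
      solubility_mg_ml = 10^runif(1, -2.5, -1),
      density_g_cm3 = runif(1, 1, 1.5),
      diffusion_m2_s = 10^runif(1, -12.3, -11.3),
      layer_um = runif(1, 2, 5)),
    disposition = disposition_params(
      vd_l = runif(1, 5, 100),
      ke_per_h = runif(1, 0.03, 0.2),
      cl_perf_ml_h = 10^runif(1, 1.7, 3.3),
      bioavailability = runif(1, 0.5, 1)),
    bins = size_bin_set(frac, diam, lag_time_h = lag),
    dose_mg = runif(1, 5, 60),
    depot_volume_ml = 0.5,
    name = paste0("random_", i))
}

mass_at <- function(sim) rowSums(sim$state)
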