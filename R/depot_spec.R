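#' Physicochemical parameters of the depot drug
#'
#' @param solubility_mg_ml aqueous solubility `S` at the injection site,
#'   mg/mL.
#' @param density_g_cm3 solid (crystal) density `rho`, g/cm^3.
#' @param diffusion_m2_s diffusion coefficient `D` of the dissolved drug in
#'   the depot fluid, m^2/s.
#' @param layer_um stagnant diffusion-layer thickness `h` around each
#'   particle, micrometres.
#' @return a `phys_chem_params` list.
#' @export
phys_chem_params <- function(solubility_mg_ml, density_g_cm3, diffusion_m2_s,
                             layer_um) {
  vals <- c(solubility_mg_ml, density_g_cm3, diffusion_m2_s, layer_um)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all physicochemical parameters must be positive and finite", call. = FALSE)
  }
  structure(list(solubility_mg_ml = solubility_mg_ml,
                 density_g_cm3 = density_g_cm3,
                 diffusion_m2_s = diffusion_m2_s,
                 layer_um = layer_um),
            class = "phys_chem_params")
}

#' Disposition parameters of the central compartment
#'
#' `cl_perf` is the perfusion clearance carrying regionally dissolved drug
#' from the depot into the systemic circulation (often written CL_dist in
#' dogs and CL_trans in humans). For a depot of a fraction of a millilitre
#' of muscle, perfusion clearance is on the scale of tens of mL/h (resting
#' muscle blood flow of roughly 350 mL per 100 g per minute through ~0.5 g
#' of tissue is about 100 mL/h), hence the mL/h unit here.
#'
#' @param vd_l central volume of distribution, litres.
#' @param ke_per_h first-order elimination rate constant, 1/h.
#' @param cl_perf_ml_h perfusion clearance depot -> central, mL/h.
#' @param bioavailability systemic bioavailability `F`, in `(0, 1]`.
#' @return a `disposition_params` list.
#' @export
disposition_params <- function(vd_l, ke_per_h, cl_perf_ml_h, bioavailability = 1) {
  vals <- c(vd_l, ke_per_h, cl_perf_ml_h, bioavailability)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all disposition parameters must be positive and finite", call. = FALSE)
  }
  if (bioavailability > 1) stop("bioavailability must be <= 1", call. = FALSE)
  structure(list(vd_l = vd_l, ke_per_h = ke_per_h, cl_perf_ml_h = cl_perf_ml_h,
                 bioavailability = bioavailability),
            class = "disposition_params")
}

#' Assemble a full depot-model specification
#'
#' Bundles everything one forward simulation needs: physicochemical
#' constants, disposition parameters, the size-bin set (with lag times), the
#' dose and the depot volume. Particle counts are (re)computed here from the
#' dose, bioavailability and solid density, so `bins` only needs mass
#' fractions, diameters and lag times.
#'
#' @param physchem a [phys_chem_params()] object.
#' @param disposition a [disposition_params()] object.
#' @param bins a `size_bin_set` with lag times set.
#' @param dose_mg dose in milligrams of active moiety.
#' @param depot_volume_ml volume `V_region` of the injection-site fluid, mL.
#' @param molar_conversion_factor optional scalar applied to the dose when
#'   the administered salt/ester mass differs from the active moiety
#'   (default 1: dose already expressed as active moiety).
#' @param name optional label.
#' @return a `depot_model_spec` object.
#' @export
depot_model_spec <- function(physchem, disposition, bins, dose_mg,
                             depot_volume_ml, molar_conversion_factor = 1,
                             name = NULL) {
  stopifnot(inherits(physchem, "phys_chem_params"),
            inherits(disposition, "disposition_params"),
            inherits(bins, "size_bin_set"))
  if (!is.finite(dose_mg) || dose_mg < 0) stop("dose must be >= 0", call. = FALSE)
  if (!is.finite(depot_volume_ml) || depot_volume_ml <= 0) {
    stop("depot volume must be positive", call. = FALSE)
  }
  if (!is.finite(molar_conversion_factor) || molar_conversion_factor <= 0) {
    stop("molar conversion factor must be positive", call. = FALSE)
  }
  if (any(is.na(bins$lag_time_h))) {
    stop("all bins must carry a lag time (see set_lag_times())", call. = FALSE)
  }
  dose_eff <- dose_mg * molar_conversion_factor
  if (dose_eff > 0) {
    bins <- assign_particle_counts(bins, dose_eff,
                                   disposition$bioavailability,
                                   physchem$density_g_cm3)
  }
  structure(list(name = name %||% "depot_model",
                 physchem = physchem,
                 disposition = disposition,
                 bins = bins,
                 dose_mg = dose_mg,
                 depot_volume_ml = depot_volume_ml,
                 molar_conversion_factor = molar_conversion_factor),
            class = "depot_model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.depot_model_spec <- function(x, ...) {
  cat(sprintf("depot_model_spec '%s': %d bins, dose %g mg, V_region %g mL\n",
              x$name, nrow(x$bins), x$dose_mg, x$depot_volume_ml))
  cat(sprintf("  S %.3g mg/mL | rho %.3g g/cm^3 | D %.3g m^2/s | h %g um\n",
              x$physchem$solubility_mg_ml, x$physchem$density_g_cm3,
              x$physchem$diffusion_m2_s, x$physchem$layer_um))
  cat(sprintf("  Vd %g L | ke %.4g 1/h | CL_perf %g mL/h | F %g\n",
              x$disposition$vd_l, x$disposition$ke_per_h,
              x$disposition$cl_perf_ml_h, x$disposition$bioavailability))
  invisible(x)
}

#' Normalize a model spec into the internal unit system
#'
#' All quantities are converted to the canonical system mg / mL (= cm^3) /
#' cm / h in which the dissolution and disposition equations are integrated:
#' D becomes cm^2/h, the layer thickness cm, the density mg/mL, the volume
#' of distribution mL and the diameters cm.
#'
#' @param spec a `depot_model_spec`.
#' @return a plain list of canonical-unit scalars and per-bin vectors, used
#'   by the integrator.
#' @export
unit_normalize <- function(spec) {
  stopifnot(inherits(spec, "depot_model_spec"))
  bins <- spec$bins
  dose_eff <- spec$dose_mg * spec$molar_conversion_factor
  solid0 <- bins$mass_fraction * spec$disposition$bioavailability * dose_eff
  list(
    n_bins = nrow(bins),
    S = spec$physchem$solubility_mg_ml,                       # mg/mL
    rho = convert_unit(spec$physchem$density_g_cm3, "g/cm^3", "mg/mL"),
    D = convert_unit(spec$physchem$diffusion_m2_s, "m^2/s", "cm^2/h"),
    h = convert_unit(spec$physchem$layer_um, "um", "cm"),
    vd = convert_unit(spec$disposition$vd_l, "L", "mL"),
    ke = spec$disposition$ke_per_h,
    cl_perf = spec$disposition$cl_perf_ml_h,                  # mL/h
    v_region = spec$depot_volume_ml,
    lag = bins$lag_time_h,
    n_particles = bins$particle_count,
    radius0 = convert_unit(bins$mean_diameter_um / 2, "um", "cm"),
    solid0 = solid0,
    amount = sum(solid0)                                      # F * dose, mg
  )
}

.req <- function(x, field, where) {
  if (is.null(x[[field]])) stop("missing field '", field, "' in ", where, call. = FALSE)
  x[[field]]
}

.qty <- function(x, field, where, to) {
  q <- .req(x, field, where)
  if (is.list(q)) {
    convert_unit(as.numeric(.req(q, "value", field)),
                 as.character(.req(q, "unit", field)), to)
  } else {
    as.numeric(q) # bare number: assumed already in the documented unit
  }
}

#' Read a depot-model specification from a YAML file
#'
#' The file mirrors the parameter tables field-for-field with explicit unit
#' strings; see the fixtures under `system.file("extdata", package =
#' "laidepot")` for the layout.
#'
#' @param path YAML file path.
#' @return a `depot_model_spec`.
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  pc <- .req(y, "physchem", path)
  dp <- .req(y, "disposition", path)
  bn <- .req(y, "bins", path)
  bins <- size_bin_set(mass_fraction = as.numeric(.req(bn, "mass_fraction", "bins")),
                       mean_diameter_um = as.numeric(.req(bn, "mean_diameter_um", "bins")),
                       lag_time_h = as.numeric(.req(bn, "lag_time_h", "bins")))
  depot_model_spec(
    physchem = phys_chem_params(
      solubility_mg_ml = .qty(pc, "solubility", "physchem", "mg/mL"),
      density_g_cm3 = .qty(pc, "solid_density", "physchem", "g/cm^3"),
      diffusion_m2_s = .qty(pc, "diffusion_coeff", "physchem", "m^2/s"),
      layer_um = .qty(pc, "diffusion_layer", "physchem", "um")),
    disposition = disposition_params(
      vd_l = .qty(dp, "vd", "disposition", "L"),
      ke_per_h = .qty(dp, "ke", "disposition", "1/h"),
      cl_perf_ml_h = .qty(dp, "cl_perf", "disposition", "mL/h"),
      bioavailability = as.numeric(.req(dp, "bioavailability", "disposition"))),
    bins = bins,
    dose_mg = .qty(y, "dose", path, "mg"),
    depot_volume_ml = .qty(y, "depot_volume", path, "mL"),
    molar_conversion_factor = as.numeric(y$molar_conversion_factor %||% 1),
    name = y$name %||% basename(path))
}

#' Write a depot-model specification to YAML
#'
#' @param spec a `depot_model_spec`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "depot_model_spec"))
  y <- list(
    name = spec$name,
    dose = list(value = spec$dose_mg, unit = "mg"),
    depot_volume = list(value = spec$depot_volume_ml, unit = "mL"),
    molar_conversion_factor = spec$molar_conversion_factor,
    physchem = list(
      solubility = list(value = spec$physchem$solubility_mg_ml, unit = "mg/mL"),
      solid_density = list(value = spec$physchem$density_g_cm3, unit = "g/cm^3"),
      diffusion_coeff = list(value = spec$physchem$diffusion_m2_s, unit = "m^2/s"),
      diffusion_layer = list(value = spec$physchem$layer_um, unit = "um")),
    disposition = list(
      vd = list(value = spec$disposition$vd_l, unit = "L"),
      ke = list(value = spec$disposition$ke_per_h, unit = "1/h"),
      cl_perf = list(value = spec$disposition$cl_perf_ml_h, unit = "mL/h"),
      bioavailability = spec$disposition$bioavailability),
    bins = list(
      mass_fraction = spec$bins$mass_fraction,
      mean_diameter_um = spec$bins$mean_diameter_um,
      lag_time_h = spec$bins$lag_time_h))
  yaml::write_yaml(y, path, precision = 12)
  invisible(path)
}

#' Load one of the packaged example model specifications
#'
#' Shipped fixtures: `dog_R`, `dog_T1`, `dog_T2`, `dog_R_altD` (alternative
#' dog diffusion coefficient), `human_R`, `human_T1`, `human_T2`.
#'
#' @param name fixture name (without extension).
#' @return a `depot_model_spec`.
#' @examples
#' spec <- example_spec("human_R")
#' spec$disposition$ke_per_h
#' @export
example_spec <- function(name) {
  path <- system.file("extdata", paste0(name, ".yaml"), package = "laidepot")
  if (path == "") {
    stop("no packaged spec named '", name, "'", call. = FALSE)
  }
  read_model_spec(path)
}
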