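#' Species profile for interspecies scaling
#'
#' @param name species label.
#' @param muscle_blood_flow resting muscle blood flow, mL per 100 g per
#'   minute.
#' @param cl_l_h systemic clearance, L/h (optional for the source species).
#' @param vd_l volume of distribution, L (optional for the source species).
#' @return a `species_profile` list.
#' @examples
#' species_profile("human", 73, cl_l_h = 4.95, vd_l = 391)
#' @export
species_profile <- function(name, muscle_blood_flow, cl_l_h = NA_real_,
                            vd_l = NA_real_) {
  if (!is.finite(muscle_blood_flow) || muscle_blood_flow <= 0) {
    stop("muscle blood flow must be positive", call. = FALSE)
  }
  if (!is.na(cl_l_h) && cl_l_h <= 0) stop("CL must be positive", call. = FALSE)
  if (!is.na(vd_l) && vd_l <= 0) stop("Vd must be positive", call. = FALSE)
  structure(list(name = name, muscle_blood_flow = muscle_blood_flow,
                 cl_l_h = cl_l_h, vd_l = vd_l),
            class = "species_profile")
}

#' Elimination rate constant from clearance and volume of distribution
#'
#' `ke = CL / Vd`.
#'
#' @param cl systemic clearance.
#' @param vd volume of distribution (same volume unit as `cl`'s numerator).
#' @return first-order elimination rate constant in `cl`'s inverse time
#'   unit.
#' @examples
#' ke_from_cl_vd(4.95, 391) # ~0.0127 per hour
#' @export
ke_from_cl_vd <- function(cl, vd) {
  if (any(!is.finite(cl)) || any(cl <= 0) || any(!is.finite(vd)) || any(vd <= 0)) {
    stop("cl and vd must be positive", call. = FALSE)
  }
  cl / vd
}

#' Scale a transport parameter by the muscle blood-flow ratio
#'
#' Local drug transport out of an intramuscular depot is perfusion-limited,
#' so transport parameters (the perfusion clearance and the effective
#' diffusion coefficient) translate between species in proportion to
#' resting muscle blood flow: `value * q_target / q_source`.
#'
#' @param value the parameter to scale (any linear rate or coefficient).
#' @param q_target target-species muscle blood flow, mL per 100 g per min.
#' @param q_source source-species muscle blood flow, same unit.
#' @return the scaled value.
#' @examples
#' scale_by_blood_flow(35, 73, 350) # 7.3
#' @export
scale_by_blood_flow <- function(value, q_target, q_source) {
  if (!is.finite(q_source) || q_source <= 0) {
    stop("source blood flow must be positive", call. = FALSE)
  }
  if (!is.finite(q_target) || q_target <= 0) {
    stop("target blood flow must be positive", call. = FALSE)
  }
  value * (q_target / q_source)
}

#' Build a human model specification from a dog-fitted one
#'
#' Keeps everything formulation-specific (size bins, per-bin lag times,
#' mass fractions, dose, bioavailability, depot volume, solubility, density,
#' diffusion-layer thickness) and replaces the transport and disposition
#' parameters: the perfusion clearance and the diffusion coefficient are
#' scaled by the muscle blood-flow ratio, the volume of distribution is
#' taken from the human profile and `ke = CL / Vd` from the human systemic
#' clearance. Lag times are carried across species unchanged, a modelling
#' assumption (the delays are treated as formulation properties).
#'
#' @param dog_spec the fitted source-species `depot_model_spec`.
#' @param human_profile a [species_profile()] with `cl_l_h` and `vd_l` set.
#' @param dog_profile a [species_profile()] for the source species.
#' @return a `depot_model_spec` for the target species.
#' @export
build_human_spec <- function(dog_spec, human_profile, dog_profile) {
  stopifnot(inherits(dog_spec, "depot_model_spec"),
            inherits(human_profile, "species_profile"),
            inherits(dog_profile, "species_profile"))
  if (is.na(human_profile$cl_l_h) || is.na(human_profile$vd_l)) {
    stop("human profile must provide CL and Vd", call. = FALSE)
  }
  q_h <- human_profile$muscle_blood_flow
  q_d <- dog_profile$muscle_blood_flow
  pc <- dog_spec$physchem
  physchem <- phys_chem_params(
    solubility_mg_ml = pc$solubility_mg_ml,
    density_g_cm3 = pc$density_g_cm3,
    diffusion_m2_s = scale_by_blood_flow(pc$diffusion_m2_s, q_h, q_d),
    layer_um = pc$layer_um)
  disposition <- disposition_params(
    vd_l = human_profile$vd_l,
    ke_per_h = ke_from_cl_vd(human_profile$cl_l_h, human_profile$vd_l),
    cl_perf_ml_h = scale_by_blood_flow(dog_spec$disposition$cl_perf_ml_h, q_h, q_d),
    bioavailability = dog_spec$disposition$bioavailability)
  depot_model_spec(
    physchem = physchem,
    disposition = disposition,
    bins = size_bin_set(dog_spec$bins$mass_fraction,
                        dog_spec$bins$mean_diameter_um,
                        lag_time_h = dog_spec$bins$lag_time_h),
    dose_mg = dog_spec$dose_mg,
    depot_volume_ml = dog_spec$depot_volume_ml,
    molar_conversion_factor = dog_spec$molar_conversion_factor,
    name = paste0(dog_spec$name, "_", human_profile$name))
}
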