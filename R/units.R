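#' Convert a physical quantity between unit labels
#'
#' Supports the unit labels used in model-spec files: lengths (`um`, `mm`,
#' `cm`, `m`), volumes (`mL`, `cm^3`, `L`, `m^3`), times (`s`, `min`, `h`,
#' `day`), masses (`ng`, `ug`, `mg`, `g`), diffusion coefficients (`m^2/s`,
#' `cm^2/s`, `cm^2/h`), flows (`mL/h`, `L/h`, `mL/min`, `L/min`),
#' concentrations/densities (`mg/mL`, `g/cm^3`, `g/L`, `ug/mL`, `ng/mL`,
#' `kg/m^3`) and first-order rates (`1/h`, `1/s`, `1/min`, `1/day`).
#' Conversion is only allowed within a dimension class.
#'
#' @param value numeric vector.
#' @param from,to unit labels.
#' @return `value` expressed in `to` units.
#' @examples
#' convert_unit(1.17e-11, "m^2/s", "cm^2/h") # 4.212e-4
#' convert_unit(3, "um", "cm")
#' @export
convert_unit <- function(value, from, to) {
  if (identical(from, to)) return(value)
  fi <- .unit_table[[from]]
  ti <- .unit_table[[to]]
  if (is.null(fi)) stop("unknown unit label: '", from, "'", call. = FALSE)
  if (is.null(ti)) stop("unknown unit label: '", to, "'", call. = FALSE)
  if (fi$dim != ti$dim) {
    stop("cannot convert '", from, "' (", fi$dim, ") to '", to, "' (", ti$dim, ")",
         call. = FALSE)
  }
  value * fi$factor / ti$factor
}

# factors relative to one reference unit per dimension class
.unit_table <- list(
  `um`  = list(dim = "length", factor = 1e-4),   # ref: cm
  `mm`  = list(dim = "length", factor = 1e-1),
  `cm`  = list(dim = "length", factor = 1),
  `m`   = list(dim = "length", factor = 1e2),
  `mL`  = list(dim = "volume", factor = 1),      # ref: mL
  `cm^3` = list(dim = "volume", factor = 1),
  `L`   = list(dim = "volume", factor = 1e3),
  `m^3` = list(dim = "volume", factor = 1e6),
  `s`   = list(dim = "time", factor = 1 / 3600), # ref: h
  `min` = list(dim = "time", factor = 1 / 60),
  `h`   = list(dim = "time", factor = 1),
  `day` = list(dim = "time", factor = 24),
  `ng`  = list(dim = "mass", factor = 1e-6),     # ref: mg
  `ug`  = list(dim = "mass", factor = 1e-3),
  `mg`  = list(dim = "mass", factor = 1),
  `g`   = list(dim = "mass", factor = 1e3),
  `m^2/s`  = list(dim = "diffusivity", factor = 3.6e7), # ref: cm^2/h
  `cm^2/s` = list(dim = "diffusivity", factor = 3600),
  `cm^2/h` = list(dim = "diffusivity", factor = 1),
  `mL/h`   = list(dim = "flow", factor = 1),     # ref: mL/h
  `L/h`    = list(dim = "flow", factor = 1e3),
  `mL/min` = list(dim = "flow", factor = 60),
  `L/min`  = list(dim = "flow", factor = 6e4),
  `mg/mL`  = list(dim = "concentration", factor = 1), # ref: mg/mL
  `g/cm^3` = list(dim = "concentration", factor = 1e3),
  `g/L`    = list(dim = "concentration", factor = 1),
  `ug/mL`  = list(dim = "concentration", factor = 1e-3),
  `ng/mL`  = list(dim = "concentration", factor = 1e-6),
  `kg/m^3` = list(dim = "concentration", factor = 1),
  `1/h`   = list(dim = "rate", factor = 1),      # ref: 1/h
  `1/s`   = list(dim = "rate", factor = 3600),
  `1/min` = list(dim = "rate", factor = 60),
  `1/day` = list(dim = "rate", factor = 1 / 24)
)
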