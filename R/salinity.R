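#' Admissible experimental settings
#'
#' The four broad categories of experimental setting distinguished by the
#' meta-analysis: open-field trials, potted plants kept outdoors, pots in a
#' greenhouse, and pots in a climate-controlled growth chamber.
#'
#' @return Character vector of the four setting labels.
#' @export
setting_levels <- function() {
  c("field", "outdoor_pots", "greenhouse", "climate_chamber")
}

#' Admissible response variables
#'
#' Growth, yield and physiological variables tracked by the pipeline.
#' `height`, `shoot_dw` and `root_dw` are growth variables and may carry a
#' developmental-stage label (`vegetative` or `reproductive`); all other
#' variables use stage `none`. `chlorophyll`, `proline` and `sodium` are
#' metabolite/ion concentrations and carry a `concentration_basis`
#' (dry or fresh weight).
#'
#' @return Character vector of variable names.
#' @export
variable_levels <- function() {
  c("height", "shoot_dw", "root_dw", "grain_yield", "tkw",
    "n_spikes", "n_grains", "chlorophyll", "proline", "sodium")
}

#' @rdname variable_levels
#' @export
growth_variables <- function() c("height", "shoot_dw", "root_dw")

#' @rdname variable_levels
#' @export
metabolite_variables <- function() c("chlorophyll", "proline", "sodium")

#' Admissible salinity units
#'
#' Salinity of a growing medium or irrigation solution may be reported as
#' electrical conductivity (dS/m), as molar NaCl concentration, or as ppm
#' NaCl.
#'
#' @return Character vector of unit codes.
#' @export
salinity_units <- function() {
  c("dS_per_m", "mol_per_L_NaCl", "ppm_NaCl")
}

# dS/m per unit of each salinity measure; 1 M NaCl = 98 dS/m and
# 1000 ppm NaCl = 1.66 dS/m, extrapolated linearly.
.ec_factors <- c(dS_per_m = 1, mol_per_L_NaCl = 98, ppm_NaCl = 1.66 / 1000)

#' Convert a salinity measurement to electrical conductivity
#'
#' Converts salinity reported in any admissible unit to electrical
#' conductivity in dS/m using linear conversion factors: 1 M NaCl is
#' equivalent to 98 dS/m and 1000 ppm NaCl to 1.66 dS/m; EC values pass
#' through unchanged. Linearity across the full concentration range is
#' assumed, which is standard for NaCl at field-relevant concentrations.
#'
#' @param value Numeric vector of non-negative salinity values.
#' @param unit Character vector (recycled) of unit codes, see
#'   [salinity_units()].
#' @return Numeric vector of EC values in dS/m.
#' @examples
#' ec_from_unit(1, "mol_per_L_NaCl")   # 98
#' ec_from_unit(1000, "ppm_NaCl")      # 1.66
#' @export
ec_from_unit <- function(value, unit) {
  if (!is.numeric(value)) {
    stop("salinity `value` must be numeric", call. = FALSE)
  }
  if (any(!is.na(value) & value < 0)) {
    stop("salinity `value` must be non-negative", call. = FALSE)
  }
  unit <- rep_len(as.character(unit), length(value))
  bad <- !is.na(unit) & !unit %in% salinity_units()
  if (any(bad)) {
    stop("unknown salinity unit(s): ", paste(unique(unit[bad]), collapse = ", "),
         call. = FALSE)
  }
  unname(value * .ec_factors[unit])
}
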