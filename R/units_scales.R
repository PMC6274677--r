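# Temperature/energy scales and the Waugh-Fedin excitation-energy calibration.
#
# The method works on a "fundamental temperature" scale, i.e. thermal energy
# k_B*T (or R*T per mole), normalized to the melting point of ice so that
# T_fn = T / 273.15 is dimensionless and T_fn = 1 at 0 degC. The Waugh-Fedin
# relation E0 = c*R*T links the temperature at which a molecular motion
# starts to the activation-energy barrier that inhibits it; c is calibrated
# from the latent heat of melting of bulk ice.

#' Physical constants used throughout the package
#'
#' Returns the constants of the energy-scale arithmetic. The gas constant
#' defaults to 8.317 J/mol/K so that worked examples reproduce the published
#' wide-line NMR hydration tables digit for digit; pass `gas_constant =
#' 8.314462` for the CODATA value if preferred.
#'
#' @param boltzmann Boltzmann constant, J/K.
#' @param gas_constant molar gas constant, J/mol/K.
#' @param ice_melt_temperature melting point of ice, K.
#' @param ice_melt_heat latent heat of melting of ice, kJ/mol.
#' @return An object of class `physical_constants` (a named list).
#' @examples
#' pc <- physical_constants()
#' pc$gas_constant * pc$ice_melt_temperature / 1000  # RT at 0 degC, kJ/mol
#' @export
physical_constants <- function(boltzmann = 1.381e-23,
                               gas_constant = 8.317,
                               ice_melt_temperature = 273.15,
                               ice_melt_heat = 6.01) {
  vals <- c(boltzmann = boltzmann, gas_constant = gas_constant,
            ice_melt_temperature = ice_melt_temperature,
            ice_melt_heat = ice_melt_heat)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    hm_stop("all physical constants must be finite and strictly positive",
            "invalid_input")
  }
  structure(as.list(vals), class = "physical_constants")
}

#' Convert between Celsius and kelvin
#'
#' @param t_celsius,t_kelvin temperatures.
#' @return Numeric vector of converted temperatures.
#' @export
celsius_to_kelvin <- function(t_celsius) t_celsius + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(t_kelvin) t_kelvin - 273.15

#' Normalized fundamental temperature
#'
#' Maps absolute temperature onto the dimensionless thermal-energy scale
#' T_fn = k_B*T / (k_B * 273.15) = T / 273.15, normalized so that bulk ice
#' melts at T_fn = 1.
#'
#' @param t_kelvin absolute temperature(s), K; must be non-negative.
#' @param constants a [physical_constants()] object.
#' @return Dimensionless T_fn, same length as `t_kelvin`.
#' @examples
#' normalized_fundamental_temperature(227.15)  # -46 degC
#' @export
normalized_fundamental_temperature <- function(t_kelvin,
                                               constants = physical_constants()) {
  if (any(!is.finite(t_kelvin)) || any(t_kelvin < 0)) {
    hm_stop("absolute temperature must be finite and >= 0 K", "invalid_input")
  }
  t_kelvin / constants$ice_melt_temperature
}

#' Invert the normalized fundamental temperature scale
#'
#' @param t_fn dimensionless normalized fundamental temperature.
#' @param constants a [physical_constants()] object.
#' @return Absolute temperature, K.
#' @export
tfn_to_kelvin <- function(t_fn, constants = physical_constants()) {
  t_fn * constants$ice_melt_temperature
}

#' Energy calibration (Waugh-Fedin proportionality constant)
#'
#' @param c dimensionless proportionality constant in E0 = c*R*T.
#' @return An object of class `energy_calibration` with fields `c` and
#'   `degrees_of_freedom` (= 2c, via equipartition of 1/2 k_B T per degree).
#' @export
energy_calibration <- function(c) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0) {
    hm_stop("calibration constant c must be a single positive number",
            "invalid_input")
  }
  structure(list(c = c, degrees_of_freedom = 2 * c),
            class = "energy_calibration")
}

#' Calibrate the excitation-energy constant from a melting transition
#'
#' Applies E0 = c*R*T to a known first-order melting transition; with the
#' latent heat of bulk ice (6.01 kJ/mol at 273.15 K) this gives c = 2.65
#' (2 d.p.), i.e. about 5.3 thermally active degrees of freedom for a
#' rotating water dipole.
#'
#' @param latent_heat molar latent heat of the transition, kJ/mol.
#' @param t_melt transition temperature, K.
#' @param constants a [physical_constants()] object.
#' @return An [energy_calibration()] object; full precision is kept for all
#'   downstream arithmetic (rounding is a display concern only).
#' @examples
#' cal <- calibrate_c(6.01, 273.15)
#' round(cal$c, 2)
#' round(cal$degrees_of_freedom, 1)
#' @export
calibrate_c <- function(latent_heat, t_melt, constants = physical_constants()) {
  if (!is.finite(latent_heat) || latent_heat <= 0) {
    hm_stop("latent heat must be positive (kJ/mol)", "invalid_input")
  }
  if (!is.finite(t_melt) || t_melt <= 0) {
    hm_stop("melting temperature must be positive (K)", "invalid_input")
  }
  rt <- constants$gas_constant * t_melt / 1000  # kJ/mol
  energy_calibration(latent_heat / rt)
}

#' Molar excitation energy at a temperature
#'
#' The Waugh-Fedin estimate of the potential barrier overcome by a motion
#' that sets in at temperature T: E0m = c * R * T, in kJ/mol.
#'
#' @param t_kelvin absolute temperature(s), K; non-negative.
#' @param cal an [energy_calibration()] object.
#' @param constants a [physical_constants()] object.
#' @return Excitation energy in kJ/mol, same length as `t_kelvin`.
#' @examples
#' excitation_energy_molar(230.15, energy_calibration(2.65))  # -43 degC
#' @export
excitation_energy_molar <- function(t_kelvin, cal,
                                    constants = physical_constants()) {
  if (any(!is.finite(t_kelvin)) || any(t_kelvin < 0)) {
    hm_stop("absolute temperature must be finite and >= 0 K", "invalid_input")
  }
  stopifnot(inherits(cal, "energy_calibration"))
  cal$c * constants$gas_constant * t_kelvin / 1000
}

#' Atomic-scale excitation energy
#'
#' Unit conversion of [excitation_energy_molar()] to a per-molecule energy
#' E0a = c * k_B * T, in joule.
#'
#' @inheritParams excitation_energy_molar
#' @return Excitation energy in J per molecule.
#' @export
excitation_energy_atomic <- function(t_kelvin, cal,
                                     constants = physical_constants()) {
  if (any(!is.finite(t_kelvin)) || any(t_kelvin < 0)) {
    hm_stop("absolute temperature must be finite and >= 0 K", "invalid_input")
  }
  stopifnot(inherits(cal, "energy_calibration"))
  cal$c * constants$boltzmann * t_kelvin
}

#' Read or write the constants/calibration JSON configuration block
#'
#' The on-disk form is `{"R": 8.317, "ice_melt_heat_kJmol": 6.01,
#' "T_melt_K": 273.15}`; missing keys fall back to the defaults of
#' [physical_constants()].
#'
#' @param path JSON file path.
#' @return `read_constants_config()` returns a [physical_constants()] object;
#'   `write_constants_config()` returns `path` invisibly.
#' @export
read_constants_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  physical_constants(
    gas_constant = cfg$R %||% 8.317,
    ice_melt_heat = cfg$ice_melt_heat_kJmol %||% 6.01,
    ice_melt_temperature = cfg$T_melt_K %||% 273.15
  )
}

#' @rdname read_constants_config
#' @param constants a [physical_constants()] object to serialize.
#' @export
write_constants_config <- function(constants, path) {
  jsonlite::write_json(
    list(R = constants$gas_constant,
         ice_melt_heat_kJmol = constants$ice_melt_heat,
         T_melt_K = constants$ice_melt_temperature),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.energy_calibration <- function(x, ...) {
  cat(sprintf("Waugh-Fedin energy calibration: c = %.4f (prints as %.2f), %s = %.2f\n",
              x$c, round(x$c, 2), "degrees of freedom", x$degrees_of_freedom))
  invisible(x)
}
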