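# Heterogeneity order parameters and bound-water counts.
#
# The plateau boundaries divide the excitation-energy axis into a
# homogeneous first-shell region (the steep onset step plus the plateau) and
# a heterogeneous region above T_fne where protein-water bond energies
# approach water-water bonds. Three order parameters quantify the
# heterogeneity: HeR compares energy ranges, HeRn compares bond counts, and
# HeM is a slope-like measure from the power-series coefficients.

#' Heterogeneity ratio HeR from the plateau boundaries
#'
#' `HeR = (1 - T_fne) / (1 - T_fno)`: the fraction of the energy distance to
#' the ice melting point occupied by heterogeneous protein-water bonds. 0
#' for homogeneous binding (bulk-water limit, `T_fne = 1`), 1 for a diagram
#' without a plateau (IDP limit, `T_fne = T_fno`).
#'
#' @param t_fno,t_fne plateau start and end on the normalized fundamental
#'   temperature scale, `0 < t_fno <= t_fne <= 1`.
#' @return Dimensionless ratio in `[0, 1]`.
#' @examples
#' heterogeneity_ratio(0.832, 0.961)
#' @export
heterogeneity_ratio <- function(t_fno, t_fne) {
  if (!is.finite(t_fno) || !is.finite(t_fne) || t_fno <= 0 ||
      t_fne < t_fno || t_fne > 1 + 1e-9) {
    hm_stop("need 0 < t_fno <= t_fne <= 1", "invalid_input")
  }
  if (t_fne >= 1 - 1e-12) return(0)          # homogeneous / bulk-water limit
  if (t_fne - t_fno < 1e-12) {
    if (t_fno >= 1 - 1e-12) {
      hm_stop("t_fno = 1 with t_fne < 1: ratio undefined", "undefined_ratio")
    }
    return(1)                                # no-plateau IDP limit
  }
  (1 - t_fne) / (1 - t_fno)
}

#' First-shell (homogeneous) mobile-water fraction n_ho
#'
#' The average of all points measured on the plateau, with its standard
#' error. For a degenerate plateau (IDP limit) the value at the top of the
#' onset step is used and flagged.
#'
#' @param md a `melting_diagram`.
#' @param plateau result of [detect_plateau()]; computed if `NULL`.
#' @return A list with `value`, `error`, `n_points`, `degenerate`.
#' @export
first_shell_fraction <- function(md, plateau = NULL) {
  stopifnot(inherits(md, "melting_diagram"))
  if (is.null(plateau)) plateau <- detect_plateau(md)
  d <- md_reliable(md)
  if (isTRUE(plateau$no_plateau) || plateau$t_fne <= plateau$t_fno + 1e-12) {
    top <- which(d$t_fn > plateau$onset_t_fn)[1]
    hm_warn("degenerate plateau: using the onset step top for n_ho", "degenerate")
    return(list(value = d$n[top], error = plateau$noise_sd, n_points = 1L,
                degenerate = TRUE))
  }
  idx <- which(d$t_fn >= plateau$t_fno - 1e-12 & d$t_fn <= plateau$t_fne + 1e-12)
  v <- d$n[idx]
  list(value = mean(v),
       error = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
       n_points = length(v), degenerate = FALSE)
}

#' Heterogeneous-region mobile-water fraction n_he
#'
#' `n_he = n(highest reliable T_fn) - n_ho`, a lower bound (measurements
#' close to T_fn = 1 are unreliable, so part of the heterogeneous region may
#' be missed; published tables mark these values with ">").
#'
#' @param md a `melting_diagram`.
#' @param n_ho first-shell fraction (number or result of
#'   [first_shell_fraction()]).
#' @param high_cut lowest T_fn accepted for the high-temperature point
#'   (default 0.97).
#' @return A list with `value`, `error`, `t_fn_used`, `lower_bound = TRUE`.
#' @export
heterogeneous_fraction <- function(md, n_ho, high_cut = 0.97) {
  stopifnot(inherits(md, "melting_diagram"))
  if (is.list(n_ho)) {
    n_ho_err <- n_ho$error
    n_ho <- n_ho$value
  } else {
    n_ho_err <- NA_real_
  }
  d <- md_reliable(md)
  hi <- which(d$t_fn >= high_cut)
  if (length(hi) == 0L) {
    hm_stop(sprintf("no reliable point at T_fn >= %.3f", high_cut),
            "missing_high_T")
  }
  j <- hi[which.max(d$t_fn[hi])]
  noise <- estimate_noise_sd(d$n)
  err <- sqrt(noise^2 + (if (is.finite(n_ho_err)) n_ho_err^2 else 0))
  list(value = d$n[j] - n_ho, error = err, t_fn_used = d$t_fn[j],
       lower_bound = TRUE)
}

#' Bond-count heterogeneity ratio HeRn
#'
#' `HeRn = n_he / (n_he + n_ho)`: the fraction of all bound water molecules
#' that sit in the heterogeneous binding-energy region. Invariant to the
#' unit of its arguments (fractions or per-molecule counts).
#'
#' @param n_ho,n_he first-shell and heterogeneous-region water amounts, both
#'   non-negative and not both zero.
#' @return Dimensionless ratio in `[0, 1]`.
#' @examples
#' heterogeneity_ratio_n(226, 102)
#' @export
heterogeneity_ratio_n <- function(n_ho, n_he) {
  if (!is.finite(n_ho) || !is.finite(n_he) || n_ho < 0 || n_he < 0) {
    hm_stop("n_ho and n_he must be non-negative", "invalid_input")
  }
  if (n_ho + n_he == 0) {
    hm_stop("n_ho and n_he cannot both be zero", "undefined_ratio")
  }
  n_he / (n_he + n_ho)
}

#' Heterogeneity measure HeM
#'
#' `HeM = (B + 2C) / (1 - T_fne)`: the number of heterogeneous bonds per
#' unit of the energy range they occupy -- a slope-like quantity that, like
#' the tangent, is not confined to `[0, 1]`. Zero for an (almost)
#' equipotential molecular surface. At the homogeneous limit `T_fne = 1` the
#' measure is taken as 0 by convention and flagged with a warning.
#'
#' @param B,C power-series coefficients (anchored at `T_fne`).
#' @param t_fne plateau end, `<= 1`.
#' @return Dimensionless, non-negative for physically monotone diagrams.
#' @export
heterogeneity_measure <- function(B, C, t_fne) {
  if (!is.finite(t_fne) || t_fne > 1 + 1e-9) {
    hm_stop("t_fne must be <= 1", "invalid_input")
  }
  if (t_fne >= 1 - 1e-12) {
    hm_warn("t_fne = 1 (homogeneous limit): HeM set to 0 by convention",
            "homogeneous_limit")
    return(0)
  }
  (B + 2 * C) / (1 - t_fne)
}

#' Convert a mobile-water fraction into waters per protein molecule
#'
#' Multiplies the fraction of total solvent water by the water-to-protein
#' mole ratio: `fraction * water_molarity / (concentration /
#' molecular_weight)` with the concentration in g/L.
#'
#' @param fraction mobile-water fraction (of total water).
#' @param spec a [sample_spec()].
#' @return Water molecules per protein molecule.
#' @examples
#' waters_per_molecule(0.0157, sample_spec("ERD10", 50, 29400, 260))
#' @export
waters_per_molecule <- function(fraction, spec) {
  stopifnot(inherits(spec, "sample_spec"))
  if (!is.finite(fraction) || fraction < 0) {
    hm_stop("fraction must be non-negative", "invalid_input")
  }
  protein_molarity <- spec$concentration / spec$molecular_weight  # mol/L
  fraction * spec$water_molarity / protein_molarity
}

#' Full hydration summary of a fitted melting diagram
#'
#' Assembles the order parameters, bound-water fractions and counts, and
#' excitation energies at the plateau boundaries into one report, with
#' first-order propagated uncertainties.
#'
#' @param fit an `md_fit`.
#' @param md the `melting_diagram` that was fitted.
#' @param spec a [sample_spec()] for count conversions.
#' @param cal an [energy_calibration()]; default the bulk-ice calibration.
#' @param high_cut passed to [heterogeneous_fraction()].
#' @param constants a [physical_constants()] object.
#' @return An object of class `hydration_params` with fields `her`, `her_n`,
#'   `hem`, `n_ho_fraction`, `n_he_fraction`, `n_ho_count`, `n_he_count`,
#'   `total_bound_count`, `waters_per_residue`, `e_at_tfno`, `e_at_tfne`
#'   (kJ/mol), `n_he_lower_bound`, and an `uncertainties` vector.
#' @examples
#' md <- generate_md(md_presets("ubiquitin_like"), seed = 1)
#' fit <- fit_melting_model(md)
#' summarize_hydration(fit, md, sample_spec("UBQ", 50, 8565, 76))
#' @export
summarize_hydration <- function(fit, md, spec, cal = calibrate_c(6.01, 273.15),
                                high_cut = 0.97,
                                constants = physical_constants()) {
  stopifnot(inherits(fit, "md_fit"), inherits(md, "melting_diagram"),
            inherits(spec, "sample_spec"))
  plateau <- list(t_fno = fit$t_fno, t_fne = fit$t_fne,
                  onset_t_fn = fit$onset_t_fn, no_plateau = fit$no_plateau,
                  noise_sd = fit$noise_sd)
  n_ho <- first_shell_fraction(md, plateau)
  n_he <- heterogeneous_fraction(md, n_ho, high_cut = high_cut)

  # T_fn = 1 is the physical ceiling of the melting scale (all water mobile
  # at the ice melting point); a plateau measured past 0 degC is clamped
  t_fno_eff <- min(fit$t_fno, 1)
  t_fne_eff <- min(fit$t_fne, 1)
  her <- heterogeneity_ratio(t_fno_eff, t_fne_eff)
  # first-order propagation of the boundary resolution errors
  so <- fit$param_errors[["t_fno"]]; se <- fit$param_errors[["t_fne"]]
  her_err <- if (t_fne_eff < 1 && is.finite(so) && is.finite(se)) {
    sqrt((se / (1 - t_fno_eff))^2 +
           ((1 - t_fne_eff) * so / (1 - t_fno_eff)^2)^2)
  } else NA_real_

  her_n <- heterogeneity_ratio_n(n_ho$value, max(n_he$value, 0))
  tot_f <- n_ho$value + max(n_he$value, 0)
  hern_err <- if (is.finite(n_ho$error) && is.finite(n_he$error)) {
    sqrt((n_ho$value * n_he$error)^2 + (n_he$value * n_ho$error)^2) / tot_f^2
  } else NA_real_

  hem <- withCallingHandlers(
    heterogeneity_measure(fit$B, fit$C, t_fne_eff),
    hydromelt_homogeneous_limit = function(w) invokeRestart("muffleWarning"))
  eb <- fit$param_errors[["B"]]; ec <- fit$param_errors[["C"]]
  # a coefficient constrained out of the fit (exact zero) has no fit error
  if (!is.finite(eb) && identical(fit$B, 0)) eb <- 0
  if (!is.finite(ec) && identical(fit$C, 0)) ec <- 0
  hem_err <- if (t_fne_eff < 1 && is.finite(eb) && is.finite(ec)) {
    # coefficient errors plus the plateau-end contribution d(HeM)/d(t_fne)
    se_e <- if (is.finite(se)) se else 0
    sqrt(eb^2 + 4 * ec^2 + (hem * se_e)^2) / (1 - t_fne_eff)
  } else NA_real_

  conv <- waters_per_molecule(1, spec)  # waters/protein per unit fraction
  n_ho_count <- n_ho$value * conv
  n_he_count <- max(n_he$value, 0) * conv

  e_o <- excitation_energy_molar(tfn_to_kelvin(t_fno_eff, constants), cal,
                                 constants)
  e_e <- excitation_energy_molar(tfn_to_kelvin(t_fne_eff, constants), cal,
                                 constants)

  structure(list(
    protein_name = spec$protein_name,
    her = her, her_n = her_n, hem = hem,
    n_ho_fraction = n_ho$value, n_he_fraction = n_he$value,
    n_ho_count = n_ho_count, n_he_count = n_he_count,
    total_bound_count = n_ho_count + n_he_count,
    waters_per_residue = n_ho_count / spec$residue_count,
    e_at_tfno = e_o, e_at_tfne = e_e,
    n_he_lower_bound = TRUE,
    t_fno = t_fno_eff, t_fne = t_fne_eff,
    onset_t_fn = fit$onset_t_fn, onset_celsius = fit$onset_celsius,
    no_plateau = fit$no_plateau,
    high_t_fn_used = n_he$t_fn_used,
    uncertainties = c(
      her = her_err, her_n = hern_err, hem = hem_err,
      n_ho_fraction = n_ho$error, n_he_fraction = n_he$error,
      n_ho_count = if (is.finite(n_ho$error)) n_ho$error * conv else NA_real_,
      n_he_count = if (is.finite(n_he$error)) n_he$error * conv else NA_real_,
      t_fno = so, t_fne = se
    )
  ), class = "hydration_params")
}

#' @export
print.hydration_params <- function(x, ...) {
  u <- x$uncertainties
  cat(sprintf("Hydration parameters: %s\n", x$protein_name))
  cat(sprintf("  T_fno = %s   T_fne = %s   HeR = %s\n",
              format_paren(x$t_fno, u[["t_fno"]]),
              format_paren(x$t_fne, u[["t_fne"]]),
              format_paren(x$her, u[["her"]])))
  cat(sprintf("  n_ho = %s (fraction), %.0f waters/protein (%.1f per residue)\n",
              format_paren(x$n_ho_fraction, u[["n_ho_fraction"]]),
              x$n_ho_count, x$waters_per_residue))
  cat(sprintf("  n_he > %s (fraction), > %.0f waters/protein (lower bound)\n",
              format_paren(x$n_he_fraction, u[["n_he_fraction"]]),
              x$n_he_count))
  cat(sprintf("  total bound = %.0f waters/protein   HeRn = %s   HeM = %.3g\n",
              x$total_bound_count, format_paren(x$her_n, u[["her_n"]]), x$hem))
  cat(sprintf("  excitation energies: %.3f kJ/mol at T_fno, %.3f kJ/mol at T_fne\n",
              x$e_at_tfno, x$e_at_tfne))
  if (x$no_plateau) cat("  NOTE: no plateau (IDP limit); HeR = 1 by convention\n")
  invisible(x)
}

#' Serialize hydration parameters to JSON
#'
#' Writes every `hydration_params` field plus provenance (fit window,
#' tolerances, seed) supplied via `provenance`.
#'
#' @param params a `hydration_params`.
#' @param path output path.
#' @param provenance named list recorded under a `provenance` key.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path, provenance = list()) {
  x <- unclass(params)
  x$uncertainties <- as.list(x$uncertainties)
  x$provenance <- provenance
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
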