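# Assembly of per-temperature mobile fractions into a melting diagram (MD):
# the mobile-water fraction n as a function of temperature, carried on the
# kelvin and normalized fundamental-temperature (T_fn = T/273.15) scales.

#' Sample specification for count conversions
#'
#' @param protein_name text label.
#' @param concentration protein concentration, mg/mL.
#' @param molecular_weight protein molecular weight, Da.
#' @param residue_count number of amino-acid residues.
#' @param water_molarity solvent water molarity, mol/L (55.35 for pure water
#'   near 0 degC).
#' @param water_mass_fraction optional mass fraction of water in the sample;
#'   when given, the water molarity is derived from it instead.
#' @return An object of class `sample_spec`.
#' @examples
#' sample_spec("UBQ", 50, 8565, 76)
#' @export
sample_spec <- function(protein_name, concentration, molecular_weight,
                        residue_count, water_molarity = 55.35,
                        water_mass_fraction = NULL) {
  num <- c(concentration = concentration, molecular_weight = molecular_weight,
           residue_count = residue_count, water_molarity = water_molarity)
  for (nm in names(num)) {
    if (!is.finite(num[[nm]]) || num[[nm]] <= 0) {
      hm_stop(sprintf("sample_spec field '%s' must be positive", nm),
              "invalid_input")
    }
  }
  if (residue_count != round(residue_count)) {
    hm_stop("residue_count must be an integer", "invalid_input")
  }
  if (!is.null(water_mass_fraction)) {
    if (!is.finite(water_mass_fraction) || water_mass_fraction <= 0 ||
        water_mass_fraction > 1) {
      hm_stop("water_mass_fraction must be in (0, 1]", "invalid_input")
    }
    # grams of water per litre of solution ~ 1000 * density * fraction;
    # unit density assumed (dilute aqueous solution).
    water_molarity <- 1000 * water_mass_fraction / 18.015
  }
  structure(list(protein_name = protein_name, concentration = concentration,
                 molecular_weight = molecular_weight,
                 residue_count = as.integer(residue_count),
                 water_molarity = water_molarity,
                 water_mass_fraction = water_mass_fraction),
            class = "sample_spec")
}

#' Build a melting diagram from (temperature, fraction) points
#'
#' Sorts the points by temperature, computes the normalized fundamental
#' temperature T_fn = T/273.15, validates ranges, and flags the band between
#' -1 and 0 degC as unreliable (measurements there are dominated by the bulk
#' ice transition and are excluded from fitting by default).
#'
#' @param points a data.frame (or coercible) with columns `temperature_k`,
#'   `n`, and optionally `n_err`; or a list of numeric vectors.
#' @param sample_id text identifier carried in the result.
#' @param constants a [physical_constants()] object.
#' @return A `melting_diagram`: a data.frame with columns `temperature`
#'   (K), `t_fn`, `n`, `n_err`, `reliable`, plus `sample_id` and `metadata`
#'   attributes.
#' @examples
#' md <- build_melting_diagram(data.frame(
#'   temperature_k = seq(210, 270, by = 10),
#'   n = c(0, 0, 0.02, 0.02, 0.02, 0.03, 0.04)), "toy")
#' @export
build_melting_diagram <- function(points, sample_id = "",
                                  constants = physical_constants()) {
  pts <- as.data.frame(points)
  if (!all(c("temperature_k", "n") %in% names(pts))) {
    hm_stop("points need columns 'temperature_k' and 'n'", "invalid_input")
  }
  if (nrow(pts) < 5L) {
    hm_stop("a melting diagram needs at least 5 points", "invalid_input")
  }
  if (anyDuplicated(pts$temperature_k)) {
    hm_stop("duplicate temperatures in melting-diagram input", "invalid_input")
  }
  if (any(!is.finite(pts$temperature_k)) || any(pts$temperature_k <= 0)) {
    hm_stop("temperatures must be finite and positive (K)", "invalid_input")
  }
  if (any(!is.finite(pts$n))) {
    hm_stop("mobile fractions must be finite", "invalid_input")
  }
  if (any(pts$n < -0.02) || any(pts$n > 1.10)) {
    hm_stop("mobile fractions outside [-0.02, 1.10]; check normalization",
            "invalid_input")
  }
  neg <- pts$n < 0
  if (any(neg)) {
    hm_warn(sprintf("%d small negative fraction(s) clamped to 0 (noise)",
                    sum(neg)), "clamped")
    pts$n[neg] <- 0
  }
  if (is.null(pts$n_err)) pts$n_err <- NA_real_
  o <- order(pts$temperature_k)
  t_c <- kelvin_to_celsius(pts$temperature_k[o])
  md <- data.frame(
    temperature = pts$temperature_k[o],
    t_fn = normalized_fundamental_temperature(pts$temperature_k[o], constants),
    n = pts$n[o],
    n_err = pts$n_err[o],
    reliable = !(t_c > -1 & t_c < 0)
  )
  structure(md, class = c("melting_diagram", "data.frame"),
            sample_id = sample_id, metadata = list())
}

#' @export
print.melting_diagram <- function(x, ...) {
  cat(sprintf("Melting diagram '%s': %d points, %.1f to %.1f degC (T_fn %.3f-%.3f)\n",
              attr(x, "sample_id"), nrow(x),
              kelvin_to_celsius(min(x$temperature)),
              kelvin_to_celsius(max(x$temperature)),
              min(x$t_fn), max(x$t_fn)))
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat(sprintf("... %d more rows\n", nrow(x) - 8L))
  invisible(x)
}

# Reliable points only, as a plain data.frame.
md_reliable <- function(md) as.data.frame(md)[md$reliable, , drop = FALSE]

#' Assemble a melting diagram from a series of FID files
#'
#' Runs the full reduction for every file in a manifest: read the trace,
#' decompose it ([decompose_fid()]), Curie-correct the slow amplitude to the
#' reference temperature ([curie_correct()]), normalize by the total-proton
#' reference ([mobile_fraction()]), and build the diagram. Per-file
#' provenance (file, temperature, decay constants, residual) is stored in
#' the `metadata` attribute. A file that cannot be read or fit is dropped
#' with a warning; the run fails if fewer than 5 usable points remain.
#'
#' @param manifest path to a manifest CSV with a `file` column (paths are
#'   resolved relative to the manifest), or a data.frame of the same shape.
#' @param acquisition an [acquisition_spec()] applied to every trace.
#' @param config list: `total_reference` (Curie-corrected total-proton
#'   amplitude; required), `curie_reference` (reference temperature, K;
#'   default 273.15), `reference_source` ("above_melting" or "gravimetric",
#'   recorded in metadata), `model_config` passed to [decompose_fid()].
#' @param sample_id text identifier.
#' @return A `melting_diagram`.
#' @export
from_fid_series <- function(manifest, acquisition = acquisition_spec(),
                            config = list(), sample_id = "") {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) {
      hm_stop(sprintf("manifest not found: %s", manifest), "invalid_input")
    }
    base <- dirname(manifest)
    man <- utils::read.csv(manifest, comment.char = "#",
                           stringsAsFactors = FALSE)
  } else {
    base <- "."
    man <- as.data.frame(manifest)
  }
  if (is.null(man$file) || nrow(man) == 0L) {
    hm_stop("manifest is empty or lacks a 'file' column", "invalid_input")
  }
  total_reference <- config$total_reference
  if (is.null(total_reference)) {
    hm_stop("config$total_reference (total-proton amplitude) is required",
            "invalid_input")
  }
  t_ref <- config$curie_reference %||% 273.15

  rows <- list(); prov <- list(); failed <- character()
  for (i in seq_len(nrow(man))) {
    path <- man$file[i]
    if (!file.exists(path)) path <- file.path(base, man$file[i])
    res <- tryCatch({
      tr <- read_fid(path, acquisition = acquisition)
      cmp <- decompose_fid(tr, config$model_config %||% list())
      slow_c <- curie_correct(cmp$slow_amplitude_t0, tr$temperature, t_ref)
      n <- mobile_fraction(slow_c, total_reference)
      list(row = data.frame(temperature_k = tr$temperature, n = n),
           prov = list(file = man$file[i], temperature_k = tr$temperature,
                       tau_f = cmp$fast_decay_constant,
                       tau_s = cmp$slow_decay_time,
                       residual_rms = cmp$fit_residual_rms))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, sprintf("%s (%s)", man$file[i],
                                  conditionMessage(res)))
    } else {
      rows[[length(rows) + 1L]] <- res$row
      prov[[length(prov) + 1L]] <- res$prov
    }
  }
  if (length(failed) > 0L) {
    hm_warn(sprintf("excluded %d trace(s): %s", length(failed),
                    paste(failed, collapse = "; ")), "excluded_traces")
  }
  if (length(rows) < 5L) {
    hm_stop(sprintf("only %d usable traces after exclusions (need >= 5)",
                    length(rows)), "invalid_input")
  }
  md <- build_melting_diagram(do.call(rbind, rows), sample_id = sample_id)
  attr(md, "metadata") <- list(
    traces = prov, failed = failed,
    total_reference = total_reference, curie_reference = t_ref,
    reference_source = config$reference_source %||% "above_melting"
  )
  md
}
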