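# Plain-text readers and writers. All formats are UTF-8 CSV with '.' decimal
# separator; '#'-prefixed key=value lines carry metadata. Every writer's
# output is accepted by its reader and reproduces the in-memory object.

read_hash_metadata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (l in meta_lines) {
    kv <- regmatches(l, regexec("^#\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", l))[[1]]
    if (length(kv) == 3L) {
      v <- trimws(kv[3])
      num <- suppressWarnings(as.numeric(v))
      meta[[kv[2]]] <- if (!is.na(num)) num else v
    }
  }
  meta
}

#' Read and write FID trace files
#'
#' One file per temperature: `#`-header lines `temperature_K=` and
#' `dead_time_us=`, then two CSV columns `time_us, amplitude`.
#'
#' @param path file path.
#' @param acquisition an [acquisition_spec()]; its dead time is overridden by
#'   the file header when present.
#' @return `read_fid()` returns an [fid_trace()]; `write_fid()` returns
#'   `path` invisibly.
#' @export
read_fid <- function(path, acquisition = acquisition_spec()) {
  if (!file.exists(path)) {
    hm_stop(sprintf("FID file not found: %s", path), "invalid_input")
  }
  meta <- read_hash_metadata(path)
  if (is.null(meta$temperature_K) || !is.numeric(meta$temperature_K)) {
    hm_stop(sprintf("FID file %s lacks a '# temperature_K=' header", path),
            "invalid_input")
  }
  if (!is.null(meta$dead_time_us) && is.numeric(meta$dead_time_us)) {
    acquisition$dead_time <- meta$dead_time_us
  }
  dat <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("time_us", "amplitude") %in% names(dat))) {
    hm_stop(sprintf("FID file %s needs columns time_us, amplitude", path),
            "invalid_input")
  }
  fid_trace(dat$time_us, dat$amplitude, meta$temperature_K, acquisition)
}

#' @rdname read_fid
#' @param trace an [fid_trace()] to write.
#' @export
write_fid <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# temperature_K=%.10g", trace$temperature),
    sprintf("# dead_time_us=%.10g", trace$acquisition$dead_time),
    "time_us,amplitude"
  ), con)
  utils::write.table(
    data.frame(time_us = trace$time, amplitude = trace$amplitude),
    con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write melting-diagram CSV files
#'
#' Columns `temperature_C, n, n_err` or `temperature_K, n, n_err` (the unit
#' is declared by the column name; header row mandatory); metadata as
#' `#`-prefixed `key=value` lines (`sample_id`, `concentration_mg_ml`,
#' `molecular_weight_da`, `residue_count`, ...).
#'
#' @param path file path.
#' @return `read_md_csv()` returns a `melting_diagram` with file metadata in
#'   its `metadata` attribute; `write_md_csv()` returns `path` invisibly.
#' @export
read_md_csv <- function(path) {
  if (!file.exists(path)) {
    hm_stop(sprintf("melting-diagram file not found: %s", path),
            "invalid_input")
  }
  meta <- read_hash_metadata(path)
  dat <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if ("temperature_K" %in% names(dat)) {
    tk <- dat$temperature_K
  } else if ("temperature_C" %in% names(dat)) {
    tk <- celsius_to_kelvin(dat$temperature_C)
  } else {
    hm_stop(sprintf("%s needs a temperature_C or temperature_K column", path),
            "invalid_input")
  }
  pts <- data.frame(temperature_k = tk, n = dat$n)
  if (!is.null(dat$n_err)) pts$n_err <- dat$n_err
  md <- build_melting_diagram(pts,
                              sample_id = as.character(meta$sample_id %||% ""))
  attr(md, "metadata") <- meta
  md
}

#' @rdname read_md_csv
#' @param md a `melting_diagram`.
#' @param unit `"C"` or `"K"` temperature column on disk.
#' @param metadata named list written as `#` header lines (merged over the
#'   diagram's own metadata).
#' @export
write_md_csv <- function(md, path, unit = c("C", "K"), metadata = list()) {
  unit <- match.arg(unit)
  meta <- utils::modifyList(
    list(sample_id = attr(md, "sample_id")),
    metadata)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    v <- meta[[k]]
    if (is.numeric(v)) v <- sprintf("%.10g", v)
    if (length(v) == 1L && is.character(v)) {
      writeLines(sprintf("# %s=%s", k, v), con)
    }
  }
  if (unit == "C") {
    out <- data.frame(temperature_C = kelvin_to_celsius(md$temperature),
                      n = md$n, n_err = md$n_err)
  } else {
    out <- data.frame(temperature_K = md$temperature, n = md$n,
                      n_err = md$n_err)
  }
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write sample-specification JSON
#'
#' Keys: `protein_name`, `concentration_mg_ml`, `molecular_weight_da`,
#' `residue_count`, `water_molarity` (optional), `water_mass_fraction`
#' (optional).
#'
#' @param path JSON file path.
#' @return `read_sample_spec()` returns a [sample_spec()];
#'   `write_sample_spec()` returns `path` invisibly.
#' @export
read_sample_spec <- function(path) {
  if (!file.exists(path)) {
    hm_stop(sprintf("sample spec not found: %s", path), "invalid_input")
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in c("protein_name", "concentration_mg_ml", "molecular_weight_da",
              "residue_count")) {
    if (is.null(j[[k]])) {
      hm_stop(sprintf("sample spec %s is missing field '%s'", path, k),
              "invalid_input")
    }
  }
  sample_spec(j$protein_name, j$concentration_mg_ml, j$molecular_weight_da,
              j$residue_count,
              water_molarity = j$water_molarity %||% 55.35,
              water_mass_fraction = j$water_mass_fraction)
}

#' @rdname read_sample_spec
#' @param spec a [sample_spec()].
#' @export
write_sample_spec <- function(spec, path) {
  jsonlite::write_json(
    list(protein_name = spec$protein_name,
         concentration_mg_ml = spec$concentration,
         molecular_weight_da = spec$molecular_weight,
         residue_count = spec$residue_count,
         water_molarity = spec$water_molarity),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
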