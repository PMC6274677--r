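# Internal helpers: classed conditions, seeded RNG, uncertainty notation.

hm_stop <- function(msg, class, ...) {
  stop(errorCondition(
    msg,
    class = c(paste0("hydromelt_", class), "hydromelt_error"),
    ...
  ))
}

hm_warn <- function(msg, class = "warning") {
  warning(warningCondition(
    msg,
    class = c(paste0("hydromelt_", class), "hydromelt_warning")
  ))
}

#' Evaluate an expression with a local, restored RNG state
#'
#' All stochastic routines in the package take an explicit `seed`; no global
#' random state leaks in or out.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    hm_stop("`seed` must be a single integer", "invalid_input")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Format a value with its uncertainty in last-digit notation
#'
#' Renders `value (error)` with the error expressed in units of the last
#' printed digit, e.g. `0.832 (4)` for 0.832 +/- 0.004, the convention used
#' in wide-line NMR hydration tables.
#'
#' @param value numeric value.
#' @param error numeric one-sigma uncertainty (same units as `value`).
#' @param digits optional number of decimal places; by default chosen so the
#'   error maps to 1--19 units of the last digit.
#' @return A character string.
#' @examples
#' format_paren(0.832, 0.004)
#' format_paren(226, 3)
#' @export
format_paren <- function(value, error, digits = NULL) {
  if (!is.finite(value)) return(NA_character_)
  if (!is.finite(error) || error <= 0) {
    return(format(value, trim = TRUE))
  }
  if (is.null(digits)) {
    digits <- max(0L, -floor(log10(error)))
    if (round(error * 10^digits) >= 20) digits <- digits - 1L
    digits <- max(0L, digits)
  }
  err_units <- max(1L, as.integer(round(error * 10^digits)))
  sprintf("%.*f (%d)", digits, round(value, digits), err_units)
}

#' Parse last-digit uncertainty notation
#'
#' Inverse of [format_paren()]: `"0.832 (4)"` becomes value 0.832 with
#' error 0.004; `">102 (33)"` is parsed with a lower-bound flag.
#'
#' @param x character string like `"0.23 (2)"`.
#' @return A list with `value`, `error`, and `lower_bound` (logical).
#' @examples
#' parse_paren("0.961 (5)")
#' @export
parse_paren <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  s <- trimws(x)
  lower <- startsWith(s, ">")
  if (lower) s <- trimws(sub("^>", "", s))
  m <- regmatches(s, regexec("^([-+0-9.eE]+)\\s*(?:\\(([0-9]+)\\))?$", s))[[1]]
  if (length(m) == 0L || m[2] == "") {
    hm_stop(sprintf("cannot parse uncertainty notation: '%s'", x), "invalid_input")
  }
  value <- as.numeric(m[2])
  error <- NA_real_
  if (length(m) >= 3L && nzchar(m[3])) {
    dec <- regmatches(m[2], regexec("\\.([0-9]+)$", m[2]))[[1]]
    ndec <- if (length(dec) >= 2L) nchar(dec[2]) else 0L
    error <- as.numeric(m[3]) * 10^(-ndec)
  }
  list(value = value, error = error, lower_bound = lower)
}

# Robust noise-level estimate for a (possibly trended) series: successive
# differences cancel smooth structure; MAD resists the onset step.
estimate_noise_sd <- function(n) {
  if (length(n) < 3L) return(0)
  stats::mad(diff(n)) / sqrt(2)
}

trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
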