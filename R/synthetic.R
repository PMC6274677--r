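# Synthetic ground-truth generators. The generator is the forward model of
# everything the analysis assumes: a melting diagram that is zero below a
# sharp onset, rises to the plateau level A across one narrow onset bin,
# stays flat between T_fno and T_fne, and rises as a power series above; and
# two-component FIDs whose slow amplitude tracks n with Curie 1/T scaling.
# Every stochastic routine takes an explicit seed and is bit-reproducible.

#' Ground truth for a synthetic melting diagram
#'
#' @param onset_t_fn onset of melting (T_fn); the step rises linearly from
#'   here to `t_fno`.
#' @param A plateau level (mobile fraction).
#' @param t_fno,t_fne plateau boundaries, `onset_t_fn <= t_fno <= t_fne`.
#' @param B,C,D power-series coefficients of the rise above `t_fne`
#'   (anchored at `t_fne`).
#' @param noise_sd homoscedastic Gaussian noise on n (default 0.002, the
#'   point scatter of a well-averaged wide-line measurement).
#' @param grid T_fn sampling grid; default 35 temperatures from -70 to
#'   -1 degC, the reliable measurement window.
#' @param seed integer seed stored with the truth.
#' @return An object of class `md_truth`.
#' @export
md_truth <- function(onset_t_fn, A, t_fno, t_fne, B = 0, C = 0, D = 0,
                     noise_sd = 0.002,
                     grid = default_tfn_grid(), seed = 1L) {
  if (!(onset_t_fn <= t_fno && t_fno <= t_fne)) {
    hm_stop("need onset_t_fn <= t_fno <= t_fne", "invalid_input")
  }
  if (noise_sd < 0) hm_stop("noise_sd must be >= 0", "invalid_input")
  if (A < 0) hm_stop("A must be >= 0", "invalid_input")
  if (any(diff(grid) <= 0)) {
    hm_stop("grid must be strictly increasing", "invalid_input")
  }
  structure(list(onset_t_fn = onset_t_fn, A = A, t_fno = t_fno,
                 t_fne = t_fne, B = B, C = C, D = D,
                 anchors = c(t_fn1 = t_fne, t_fn2 = t_fne),
                 noise_sd = noise_sd, grid = grid, seed = as.integer(seed)),
            class = "md_truth")
}

#' Default synthetic T_fn grid
#'
#' 35 temperatures from -70 to -1 degC on the normalized fundamental scale.
#'
#' @param from,to temperature range, degC.
#' @param n number of points.
#' @return Numeric T_fn grid.
#' @export
default_tfn_grid <- function(from = -70, to = -1, n = 35L) {
  normalized_fundamental_temperature(celsius_to_kelvin(seq(from, to,
                                                           length.out = n)))
}

#' Evaluate a truth object's noiseless melting curve
#'
#' @param truth an [md_truth()].
#' @param t_fn evaluation points; defaults to the truth grid.
#' @return Noiseless mobile fractions.
#' @export
truth_curve <- function(truth, t_fn = truth$grid) {
  eval_piecewise_md(t_fn, truth$onset_t_fn, truth$t_fno, truth$t_fne,
                    truth$A, truth$B, truth$C, truth$D)
}

#' Generate a synthetic melting diagram
#'
#' Samples the truth curve on its grid and adds homoscedastic Gaussian noise;
#' deterministic under `seed`.
#'
#' @param truth an [md_truth()].
#' @param seed integer seed (defaults to the seed stored in `truth`).
#' @param sample_id text identifier.
#' @return A `melting_diagram`; generation truth is kept in the `truth`
#'   entry of its `metadata` attribute.
#' @examples
#' md <- generate_md(md_presets("erd10_like"), seed = 42)
#' @export
generate_md <- function(truth, seed = truth$seed, sample_id = "synthetic") {
  stopifnot(inherits(truth, "md_truth"))
  n0 <- truth_curve(truth)
  n <- if (truth$noise_sd > 0) {
    with_seed(seed, n0 + stats::rnorm(length(n0), sd = truth$noise_sd))
  } else n0
  # tiny negative excursions below the onset are measurement noise
  md <- suppressWarnings(build_melting_diagram(
    data.frame(temperature_k = tfn_to_kelvin(truth$grid),
               n = pmin(n, 1.05),
               n_err = rep(truth$noise_sd, length(n))),
    sample_id = sample_id))
  attr(md, "metadata") <- list(truth = truth, seed = seed)
  md
}

#' Simulation settings for synthetic FID series
#'
#' @param fast_amplitude solid (immobile-proton) amplitude at t = 0,
#'   constant across temperature (protein protons).
#' @param fast_decay fast Gaussian decay constant, us.
#' @param slow_decay slow (mobile-water) decay time, us; must exceed
#'   `fast_decay`.
#' @param dead_time receiver dead time, us; sampling starts here.
#' @param t_max last sample time, us.
#' @param dt sampling interval, us.
#' @param noise_sd additive amplitude noise (same arbitrary units as the
#'   amplitudes).
#' @param curie_reference reference temperature for Curie scaling, K; the
#'   slow amplitude at temperature T is `n * curie_reference / T` so the
#'   Curie-corrected amplitude equals n.
#' @param seed integer seed.
#' @return An object of class `fid_sim_spec`.
#' @export
fid_sim_spec <- function(fast_amplitude = 5, fast_decay = 12,
                         slow_decay = 400, dead_time = 8, t_max = 1600,
                         dt = 4, noise_sd = 0.002, curie_reference = 273.15,
                         seed = 1L) {
  if (fast_decay <= 0 || slow_decay <= 0) {
    hm_stop("decay constants must be positive", "invalid_input")
  }
  if (slow_decay <= fast_decay) {
    hm_stop("slow_decay must exceed fast_decay", "invalid_input")
  }
  if (dead_time <= 0 || dt <= 0 || t_max <= dead_time) {
    hm_stop("invalid sampling grid", "invalid_input")
  }
  structure(list(fast_amplitude = fast_amplitude, fast_decay = fast_decay,
                 slow_decay = slow_decay, dead_time = dead_time,
                 t_max = t_max, dt = dt, noise_sd = noise_sd,
                 curie_reference = curie_reference, seed = as.integer(seed)),
            class = "fid_sim_spec")
}

#' Generate a temperature series of synthetic FID traces
#'
#' At each grid temperature the slow amplitude is `n_truth(T_fn) *
#' curie_reference / T` (Curie law) and the fast amplitude is constant;
#' traces are sampled from the dead time onward with additive Gaussian
#' noise. Deterministic under `seed`.
#'
#' @param truth an [md_truth()].
#' @param sim an [fid_sim_spec()].
#' @param seed integer seed (defaults to the seed stored in `sim`).
#' @return A list of [fid_trace()] objects, one per grid temperature, with
#'   the truth attached as an attribute.
#' @export
generate_fid_series <- function(truth, sim = fid_sim_spec(),
                                seed = sim$seed) {
  stopifnot(inherits(truth, "md_truth"), inherits(sim, "fid_sim_spec"))
  tt <- seq(sim$dead_time, sim$t_max, by = sim$dt)
  n_true <- truth_curve(truth)
  temps <- tfn_to_kelvin(truth$grid)
  acq <- acquisition_spec(dead_time = sim$dead_time)
  with_seed(seed, {
    lapply(seq_along(temps), function(i) {
      slow_amp <- n_true[i] * sim$curie_reference / temps[i]
      y <- sim$fast_amplitude * exp(-0.5 * (tt / sim$fast_decay)^2) +
        slow_amp * exp(-tt / sim$slow_decay)
      if (sim$noise_sd > 0) {
        y <- y + stats::rnorm(length(tt), sd = sim$noise_sd)
      }
      fid_trace(tt, y, temps[i], acq)
    })
  })
}

#' Convert a ground truth to an exact fitted-model object
#'
#' Wraps the generator's true parameters in an `md_fit` so the analytic
#' differential melting diagram and model predictions of the truth itself
#' can be evaluated (the oracle in recovery and convergence checks).
#'
#' @param truth an [md_truth()].
#' @return An `md_fit` whose parameters equal the truth exactly.
#' @export
as_md_fit <- function(truth) {
  stopifnot(inherits(truth, "md_truth"))
  structure(list(
    onset_t_fn = truth$onset_t_fn,
    onset_celsius = kelvin_to_celsius(tfn_to_kelvin(truth$onset_t_fn)),
    A = truth$A, t_fno = truth$t_fno, t_fne = truth$t_fne,
    B = truth$B, C = truth$C, D = truth$D,
    t_fn1 = truth$t_fne, t_fn2 = truth$t_fne,
    param_errors = c(A = NA_real_, B = NA_real_, C = NA_real_, D = NA_real_,
                     t_fno = NA_real_, t_fne = NA_real_),
    fit_window = range(truth$grid),
    rss = 0, order = if (truth$D != 0) 3L else 2L,
    noise_sd = truth$noise_sd,
    grid_bin = stats::median(diff(truth$grid)),
    no_plateau = truth$t_fne <= truth$t_fno
  ), class = "md_fit")
}

#' Built-in ground-truth presets
#'
#' Three archetypes of hydration behaviour:
#' \describe{
#'   \item{`ubiquitin_like`}{a globular protein: onset near T_fn 0.832
#'     (-46 degC), a broad plateau 0.832--0.961 at A = 0.019, and a modest
#'     quadratic rise reaching 0.028 at T_fn 0.995.}
#'   \item{`erd10_like`}{an intrinsically disordered protein: onset near
#'     0.835, a narrow plateau 0.835--0.889 at A = 0.0157, and a steep
#'     quadratic rise (heterogeneous fraction 0.098 at T_fn 0.995).}
#'   \item{`bulk_water_like`}{pure water: a single step from 0 to 1 at
#'     T_fn = 1, no heterogeneous segment, sampled on a grid that crosses
#'     0 degC.}
#' }
#' The onset precedes the plateau start by 0.0004 T_fn units (a step of
#' ~0.01 kJ/mol width on the excitation-energy scale).
#'
#' @param name one of `"ubiquitin_like"`, `"erd10_like"`,
#'   `"bulk_water_like"`.
#' @param noise_sd noise level override (default 0.002).
#' @param seed integer seed stored in the truth.
#' @return An [md_truth()].
#' @examples
#' md_presets("ubiquitin_like")
#' @export
md_presets <- function(name, noise_sd = 0.002, seed = 1L) {
  step_width <- 0.0004  # ~0.01 kJ/mol on the excitation-energy scale
  rise_end <- 0.995     # last reliable T_fn used to anchor the rise level
  switch(name,
    ubiquitin_like = {
      t_fno <- 0.832; t_fne <- 0.961; A <- 0.019; n_he <- 0.009
      md_truth(onset_t_fn = t_fno - step_width, A = A, t_fno = t_fno,
               t_fne = t_fne, B = 0, C = n_he / (rise_end - t_fne)^2,
               noise_sd = noise_sd, seed = seed)
    },
    erd10_like = {
      t_fno <- 0.835; t_fne <- 0.889; A <- 0.0157; n_he <- 0.098
      md_truth(onset_t_fn = t_fno - step_width, A = A, t_fno = t_fno,
               t_fne = t_fne, B = 0, C = n_he / (rise_end - t_fne)^2,
               noise_sd = noise_sd, seed = seed)
    },
    bulk_water_like = {
      # sampled past 0 degC so the all-mobile region is long enough to
      # register as a plateau (n = 1, T_fn > 1)
      md_truth(onset_t_fn = 1 - step_width, A = 1, t_fno = 1, t_fne = 1,
               B = 0, C = 0, noise_sd = noise_sd,
               grid = normalized_fundamental_temperature(
                 celsius_to_kelvin(seq(-20, 7, length.out = 28L))),
               seed = seed)
    },
    hm_stop(sprintf("unknown preset '%s'", name), "invalid_input")
  )
}
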