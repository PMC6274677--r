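# Shared fixtures, built in code.

ubq_spec <- function() sample_spec("UBQ", 50, 8565, 76)
erd10_spec <- function() sample_spec("ERD10", 50, 29400, 260)

# a hand-built diagram with a known flat plateau and quadratic rise
toy_md <- function(A = 0.05, noise = 0, seed = 1) {
  t_fn <- default_tfn_grid(n = 25L)
  truth <- md_truth(0.82, A, 0.825, 0.93, B = 0, C = 2, noise_sd = noise,
                    grid = t_fn, seed = seed)
  generate_md(truth, seed = seed, sample_id = "toy")
}

# a two-component synthetic trace with known parameters
toy_trace <- function(F = 5, tau_f = 12, S = 1.2, tau_s = 400,
                      dead_time = 8, t_max = 1600, dt = 4,
                      noise = 0, seed = 1, temperature = 250) {
  tt <- seq(dead_time, t_max, by = dt)
  y <- F * exp(-0.5 * (tt / tau_f)^2) + S * exp(-tt / tau_s)
  if (noise > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(tt), sd = noise)
  }
  fid_trace(tt, y, temperature, acquisition_spec(dead_time = dead_time))
}
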