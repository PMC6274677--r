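test_that("HeR compares the energy distances to the ice melting point", {
  expect_equal(round(heterogeneity_ratio(0.832, 0.961), 2), 0.23)
  # bulk-water (homogeneous) and IDP (no-plateau) limits
  expect_equal(heterogeneity_ratio(0.85, 1.0), 0)
  expect_equal(heterogeneity_ratio(0.85, 0.85), 1)
  expect_error(heterogeneity_ratio(1.2, 1.3),
               class = "hydromelt_invalid_input")
  # within [0, 1], decreasing in t_fne, increasing in t_fno
  set.seed(3)
  for (i in 1:25) {
    o <- runif(1, 0.5, 0.98); e <- runif(1, o, 1)
    h <- heterogeneity_ratio(o, e)
    expect_gte(h, 0); expect_lte(h, 1)
    if (e + 0.005 < 1) expect_lt(heterogeneity_ratio(o, e + 0.005), h + 1e-12)
    if (o + 0.005 < e) expect_gt(heterogeneity_ratio(o + 0.005, e), h - 1e-12)
  }
})

test_that("the first-shell fraction is the plateau average", {
  flat <- build_melting_diagram(
    data.frame(temperature_k = seq(230, 270, by = 5), n = rep(0.05, 9)))
  fs <- first_shell_fraction(flat, list(t_fno = flat$t_fn[1],
                                        t_fne = flat$t_fn[9],
                                        no_plateau = FALSE, noise_sd = 0))
  expect_equal(fs$value, 0.05)
  expect_equal(fs$error, 0)

  # a two-point plateau averages arithmetically
  md <- build_melting_diagram(data.frame(
    temperature_k = c(220, 230, 240, 250, 260),
    n = c(0, 0.018, 0.020, 0.05, 0.09)))
  fs2 <- first_shell_fraction(md, list(t_fno = md$t_fn[2], t_fne = md$t_fn[3],
                                       no_plateau = FALSE, noise_sd = 0))
  expect_equal(fs2$value, 0.019)
  expect_equal(fs2$n_points, 2L)

  # degenerate plateau: step top used and flagged
  expect_warning(
    fs3 <- first_shell_fraction(md, list(t_fno = md$t_fn[2],
                                         t_fne = md$t_fn[2],
                                         onset_t_fn = md$t_fn[2] - 1e-4,
                                         no_plateau = TRUE, noise_sd = 0.001)),
    class = "hydromelt_degenerate")
  expect_true(fs3$degenerate)
})

test_that("the heterogeneous fraction is a lower bound from the top point", {
  truth <- md_presets("ubiquitin_like", noise_sd = 0)
  md <- generate_md(truth)
  n_ho <- list(value = truth$A, error = 0)
  nhe <- heterogeneous_fraction(md, n_ho)
  expect_true(nhe$lower_bound)
  expect_equal(nhe$value,
               truth_curve(truth, nhe$t_fn_used) - truth$A, tolerance = 1e-12)
  expect_error(heterogeneous_fraction(md, n_ho, high_cut = 1.5),
               class = "hydromelt_missing_high_T")
  # diagram whose top point equals the plateau: nothing heterogeneous
  flat <- build_melting_diagram(
    data.frame(temperature_k = seq(250, 271, length.out = 8), n = rep(0.04, 8)))
  expect_equal(heterogeneous_fraction(flat, 0.04)$value, 0)
})

test_that("HeRn is the heterogeneous share of all bound waters", {
  expect_equal(round(heterogeneity_ratio_n(226, 102), 1), 0.3)
  expect_equal(heterogeneity_ratio_n(1, 0), 0)
  expect_equal(heterogeneity_ratio_n(0, 3), 1)
  # unit invariance: counts and fractions give the same ratio
  expect_equal(heterogeneity_ratio_n(226, 102),
               heterogeneity_ratio_n(226 / 1e4, 102 / 1e4))
  expect_error(heterogeneity_ratio_n(0, 0),
               class = "hydromelt_undefined_ratio")
})

test_that("HeM is the slope-like measure of the heterogeneous region", {
  expect_equal(heterogeneity_measure(0, 0, 0.9), 0)
  expect_equal(heterogeneity_measure(1, 0, 0.5), 2)
  expect_warning(h1 <- heterogeneity_measure(1, 2, 1),
                 class = "hydromelt_homogeneous_limit")
  expect_equal(h1, 0)
  # recovered HeM matches the generator truth within the fit uncertainty
  truth <- md_presets("erd10_like")
  md <- generate_md(truth, seed = 13)
  hp <- summarize_hydration(fit_melting_model(md), md, erd10_spec())
  hem_true <- heterogeneity_measure(truth$B, truth$C, truth$t_fne)
  expect_lt(abs(hp$hem - hem_true), 3 * hp$uncertainties[["hem"]])
})

test_that("fractions convert to per-molecule water counts", {
  # ERD10: 0.0157 of 55.35 M water against 50 mg/mL of a 29.4 kDa protein
  w <- waters_per_molecule(0.0157, erd10_spec())
  expect_lt(abs(w - 514) / 514, 0.01)
  expect_equal(waters_per_molecule(0, ubq_spec()), 0)
  # consistency: equimolar water and protein, all water bound -> 1 water each
  sp <- sample_spec("X", 55350, 1000, 10, water_molarity = 55.35)
  expect_equal(waters_per_molecule(1, sp), 1)
})

test_that("the hydration summary assembles consistent parameters", {
  truth <- md_presets("ubiquitin_like")
  md <- generate_md(truth, seed = 4)
  fit <- fit_melting_model(md)
  hp <- summarize_hydration(fit, md, ubq_spec())
  expect_s3_class(hp, "hydration_params")
  expect_equal(hp$total_bound_count, hp$n_ho_count + hp$n_he_count)
  expect_equal(hp$waters_per_residue, hp$n_ho_count / 76)
  expect_gte(hp$her, 0); expect_lte(hp$her, 1)
  expect_gte(hp$her_n, 0); expect_lte(hp$her_n, 1)
  expect_true(hp$n_he_lower_bound)
  # excitation energies are cRT at the plateau boundaries
  cal <- calibrate_c(6.01, 273.15)
  expect_equal(hp$e_at_tfno,
               excitation_energy_molar(tfn_to_kelvin(hp$t_fno), cal))
  # the seed-median HeR lands close to the published 0.23 (single draws
  # inherit ~6x the plateau-end uncertainty, so only the median is tight)
  hers <- vapply(1:30, function(s) {
    mds <- generate_md(md_presets("ubiquitin_like"), seed = s)
    summarize_hydration(fit_melting_model(mds), mds, ubq_spec())$her
  }, 0)
  expect_lt(abs(stats::median(hers) - 0.232), 0.05)
  path <- withr::local_tempfile(fileext = ".json")
  write_params_json(hp, path, provenance = list(seed = 4))
  j <- jsonlite::read_json(path)
  expect_equal(j$her, hp$her)
  expect_equal(j$provenance$seed, 4)
})

test_that("propagated HeR uncertainty reproduces published magnitudes", {
  # boundary errors (0.004, 0.005) around (0.832, 0.961) should propagate
  # to an HeR uncertainty within a factor 2 of the published 0.02
  truth <- md_presets("ubiquitin_like", noise_sd = 0)
  md <- generate_md(truth)
  fit <- fit_melting_model(md)
  fit$param_errors[["t_fno"]] <- 0.004
  fit$param_errors[["t_fne"]] <- 0.005
  hp <- summarize_hydration(fit, md, ubq_spec())
  u <- hp$uncertainties[["her"]]
  expect_gt(u, 0.01); expect_lt(u, 0.04)
  # cross-check against a brute-force Monte Carlo propagation
  set.seed(9)
  sims <- replicate(4000, {
    o <- rnorm(1, fit$t_fno, 0.004); e <- rnorm(1, fit$t_fne, 0.005)
    (1 - e) / (1 - o)
  })
  expect_lt(abs(u - sd(sims)) / sd(sims), 0.15)
})

test_that("last-digit uncertainty notation round-trips", {
  expect_equal(format_paren(0.832, 0.004), "0.832 (4)")
  expect_equal(format_paren(226, 3), "226 (3)")
  expect_equal(format_paren(0.23, 0.02), "0.23 (2)")
  p <- parse_paren("0.961 (5)")
  expect_equal(p$value, 0.961)
  expect_equal(p$error, 0.005)
  expect_false(p$lower_bound)
  p2 <- parse_paren(">102 (33)")
  expect_true(p2$lower_bound)
  expect_equal(p2$value, 102)
  expect_equal(p2$error, 33)
  for (case in list(c(0.1234, 0.0021), c(515, 13), c(2.97, 0.04))) {
    f <- format_paren(case[1], case[2])
    q <- parse_paren(f)
    expect_lt(abs(q$value - case[1]), case[2])
    expect_lt(abs(q$error - case[2]) / case[2], 0.5)
  }
})
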