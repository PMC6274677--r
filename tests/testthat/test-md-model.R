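test_that("the onset is located by interpolation near the step", {
  # dense grid: an ideal step at T_fn = 0.832 is found to grid resolution
  t_fn <- seq(0.80, 0.99, by = 5e-4)
  n <- ifelse(t_fn >= 0.832, 0.02, 0)
  md <- build_melting_diagram(data.frame(temperature_k = t_fn * 273.15, n = n))
  on <- detect_onset(md)
  expect_lt(abs(on$onset_t_fn - 0.832), 1e-3)

  expect_error(detect_onset(md, threshold = 0.5),
               class = "hydromelt_no_melting")
  flat <- build_melting_diagram(
    data.frame(temperature_k = seq(210, 260, by = 10), n = rep(0.05, 6)))
  expect_error(detect_onset(flat), class = "hydromelt_no_onset")
})

test_that("plateau detection finds the run boundaries and refines the end", {
  # flat diagram over the whole window: plateau = whole window
  flat <- build_melting_diagram(
    data.frame(temperature_k = seq(210, 260, by = 5), n = rep(0.05, 11)))
  pl <- detect_plateau(flat)
  expect_equal(pl$t_fno, flat$t_fn[1])
  expect_equal(pl$t_fne, flat$t_fn[nrow(flat)])
  expect_false(pl$no_plateau)

  # strictly rising diagram: the no-plateau (IDP) limit
  tt <- seq(210, 260, by = 5)
  steep <- build_melting_diagram(
    data.frame(temperature_k = tt, n = seq(0.01, 0.9, length.out = 11)))
  pl2 <- detect_plateau(steep, slope_tol = 0.5)
  expect_true(pl2$no_plateau)
  expect_equal(pl2$t_fno, pl2$t_fne)
  expect_equal(pl2$t_fno, pl2$onset_t_fn)
})

test_that("exact model data are refitted to numerical precision", {
  truth <- md_truth(0.8316, 0.019, 0.832, 0.961, B = 0, C = 8.0,
                    noise_sd = 0)
  fit <- fit_melting_model(generate_md(truth))
  expect_equal(fit$A, 0.019, tolerance = 1e-9)
  expect_equal(fit$t_fne, 0.961, tolerance = 1e-6)
  expect_equal(fit$B, 0, tolerance = 1e-6)
  expect_equal(fit$C, 8.0, tolerance = 1e-6)
  expect_identical(fit$t_fn1, fit$t_fne)
  expect_identical(fit$t_fn2, fit$t_fne)
  # continuity: the model equals A at the plateau end
  expect_equal(predict(fit, fit$t_fne), fit$A, tolerance = 1e-12)

  # plateau-only data: no rise terms
  flat <- build_melting_diagram(
    data.frame(temperature_k = seq(230, 270, by = 4), n = rep(0.031, 11)))
  pfl <- detect_plateau(flat)
  ffl <- fit_melting_model(flat, pfl)
  expect_equal(ffl$A, 0.031)
  expect_identical(c(ffl$B, ffl$C, ffl$D), c(0, 0, 0))
})

test_that("a kinked (linear) rise is fitted when the data demand it", {
  truth <- md_truth(0.8316, 0.019, 0.832, 0.90, B = 0.3, C = 0,
                    noise_sd = 0)
  fit <- fit_melting_model(generate_md(truth))
  expect_equal(fit$t_fne, 0.90, tolerance = 1e-4)
  expect_equal(fit$B, 0.3, tolerance = 1e-3)
  expect_equal(fit$C, 0, tolerance = 0.05)
})

test_that("analytic DMD integrates back to the melting diagram", {
  truth <- md_presets("ubiquitin_like", noise_sd = 0)
  fit <- fit_melting_model(generate_md(truth))
  dmd <- dmd_analytic(fit)
  top <- fit$fit_window[2]

  # fundamental-theorem identity over the heterogeneous region
  expect_equal(integrate_dmd(dmd, fit$t_fne, top),
               predict(fit, top) - fit$A, tolerance = 1e-9)
  # conservation over the whole window including the onset bar
  expect_equal(integrate_dmd(dmd, fit$onset_t_fn, top),
               predict(fit, top), tolerance = 1e-9)
  # the onset bar carries exactly the plateau level A
  seg <- attr(dmd, "segments")
  expect_equal(seg$area[seg$segment == "onset"], fit$A)
  expect_equal(seg$area[seg$segment == "plateau"], 0)

  # degenerate shapes
  fit0 <- fit; fit0$B <- 0; fit0$C <- 0; fit0$D <- 0
  d0 <- dmd_analytic(fit0)
  expect_true(all(d0$dn_dtfn[d0$segment %in% c("plateau", "heterogeneous")] == 0))
  fitB <- fit0; fitB$B <- 1
  dB <- dmd_analytic(fitB)
  expect_true(all(dB$dn_dtfn[dB$segment == "heterogeneous"] == 1))
})

test_that("numerical DMD is the model-free oracle of the analytic form", {
  # linear diagram: derivative is exactly 1
  t_fn <- seq(0.80, 0.99, length.out = 20)
  lin <- build_melting_diagram(
    data.frame(temperature_k = t_fn * 273.15, n = t_fn - 0.795))
  dn <- dmd_numeric(lin)
  expect_equal(dn$dn_dtfn, rep(1, nrow(lin) - 2L), tolerance = 1e-9)

  # exact quadratic data: centered differences match the analytic derivative
  truth <- md_presets("erd10_like", noise_sd = 0)
  md <- generate_md(truth)
  fit <- as_md_fit(truth)
  dn2 <- dmd_numeric(md)
  da <- dmd_analytic(fit, grid = dn2$t_fn)
  inside <- dn2$t_fn > truth$t_fne + 2 * stats::median(diff(truth$grid))
  expect_lt(max(abs(dn2$dn_dtfn[inside] - da$dn_dtfn[inside])), 1e-9)
})

test_that("centered differences converge to the analytic DMD at order >= 2", {
  # a cubic rise makes the discretization error measurable
  errs <- vapply(c(35L, 69L, 137L), function(npts) {
    grid <- default_tfn_grid(n = npts)
    truth <- md_truth(0.8316, 0.019, 0.832, 0.90, B = 0, C = 4, D = 50,
                      noise_sd = 0, grid = grid)
    md <- generate_md(truth)
    dn <- dmd_numeric(md)
    da <- dmd_analytic(as_md_fit(truth), grid = dn$t_fn)
    h <- stats::median(diff(grid))
    inside <- dn$t_fn > truth$t_fne + 2 * h & dn$t_fn < max(grid) - h
    max(abs(dn$dn_dtfn[inside] - da$dn_dtfn[inside]))
  }, 0)
  orders <- log2(errs[-3] / errs[-1])
  expect_true(all(orders >= 1.9))
})

test_that("noisy numerical DMD stays within propagated noise of the model", {
  truth <- md_presets("erd10_like")
  md <- generate_md(truth, seed = 21)
  dn <- dmd_numeric(md)
  da <- dmd_analytic(as_md_fit(truth), grid = dn$t_fn)
  h <- stats::median(diff(truth$grid))
  sd_dmd <- truth$noise_sd * sqrt(2) / (2 * h)
  inside <- dn$t_fn > truth$t_fne + 2 * h | dn$t_fn < truth$onset_t_fn - 2 * h
  expect_true(all(abs(dn$dn_dtfn[inside] - da$dn_dtfn[inside]) < 3 * sd_dmd))
})

test_that("trapezoidal integration handles simple and degenerate inputs", {
  grid <- seq(0.9, 1.0, by = 0.01)
  const <- dmd_analytic(local({
    f <- as_md_fit(md_truth(0.85, 0.02, 0.855, 0.88, B = 2, C = 0,
                            noise_sd = 0, grid = seq(0.8, 1, by = 0.01)))
    f
  }), grid = grid)
  # constant derivative k over [a, b] integrates to k (b - a)
  expect_equal(integrate_dmd(const, 0.9, 1.0), 2 * 0.1, tolerance = 1e-12)
  expect_error(integrate_dmd(const, 1.0, 0.9),
               class = "hydromelt_invalid_input")

  zero <- dmd_numeric(build_melting_diagram(
    data.frame(temperature_k = seq(220, 260, by = 5), n = rep(0, 9))))
  expect_equal(integrate_dmd(zero, min(zero$t_fn), max(zero$t_fn)), 0)
})

test_that("fits survive a JSON round trip exactly", {
  fit <- fit_melting_model(generate_md(md_presets("ubiquitin_like"), seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  fit2 <- read_fit_json(path)
  for (f in c("A", "t_fno", "t_fne", "B", "C", "D", "onset_t_fn", "rss")) {
    expect_equal(fit2[[f]], fit[[f]], tolerance = 1e-12)
  }
  expect_equal(fit2$param_errors, fit$param_errors, tolerance = 1e-12)
  expect_equal(fit2$fit_window, fit$fit_window, tolerance = 1e-12)
})
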