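test_that("diagrams are sorted, normalized and validated on construction", {
  pts <- data.frame(temperature_k = c(250, 210, 230, 270, 220),
                    n = c(0.2, 0, 0.1, 0.9, 0.05))
  md <- build_melting_diagram(pts, "s1")
  expect_s3_class(md, "melting_diagram")
  expect_true(all(diff(md$temperature) > 0))
  expect_equal(md$t_fn, md$temperature / 273.15, tolerance = 1e-9)
  # permutation invariance
  md2 <- build_melting_diagram(pts[order(pts$n), ], "s1")
  expect_equal(as.data.frame(md), as.data.frame(md2))

  expect_error(build_melting_diagram(pts[1:4, ]),
               class = "hydromelt_invalid_input")
  pts_dup <- pts; pts_dup$temperature_k[2] <- 250
  expect_error(build_melting_diagram(pts_dup),
               class = "hydromelt_invalid_input")
  pts_bad <- pts; pts_bad$n[1] <- 1.2
  expect_error(build_melting_diagram(pts_bad),
               class = "hydromelt_invalid_input")
  pts_neg <- pts; pts_neg$n[2] <- -0.01
  expect_warning(md3 <- build_melting_diagram(pts_neg),
                 class = "hydromelt_clamped")
  expect_equal(min(md3$n), 0)
})

test_that("points between -1 and 0 degC are flagged unreliable", {
  pts <- data.frame(temperature_k = celsius_to_kelvin(c(-20, -10, -5, -0.5, 1)),
                    n = c(0, 0.1, 0.2, 0.5, 1))
  md <- build_melting_diagram(pts)
  expect_identical(md$reliable, c(TRUE, TRUE, TRUE, FALSE, TRUE))
})

test_that("an ideal bulk-water diagram is a single step at T_fn = 1", {
  pts <- data.frame(
    temperature_k = c(celsius_to_kelvin(seq(-25, -5, by = 5)), 273.15),
    n = c(rep(0, 5), 1))
  md <- build_melting_diagram(pts, "bulk")
  on <- detect_onset(md)
  expect_lt(abs(on$onset_t_fn - 1), 273.15^-1 * 5 / 2 + 1e-9)
})

test_that("melting-diagram CSV files round-trip in both units", {
  md <- toy_md(noise = 0.002, seed = 5)
  for (unit in c("C", "K")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_md_csv(md, path, unit = unit,
                 metadata = list(concentration_mg_ml = 50))
    md2 <- read_md_csv(path)
    expect_equal(md2$temperature, md$temperature, tolerance = 1e-9)
    expect_equal(md2$n, md$n, tolerance = 1e-12)
    expect_equal(attr(md2, "sample_id"), attr(md, "sample_id"))
    expect_equal(attr(md2, "metadata")$concentration_mg_ml, 50)
  }
})

test_that("a diagram is assembled end to end from an FID series", {
  grid <- normalized_fundamental_temperature(
    celsius_to_kelvin(seq(-70, -1, length.out = 12)))
  truth <- md_truth(0.8316, 0.019, 0.832, 0.961, B = 0, C = 7.785,
                    noise_sd = 0, grid = grid)
  sim <- fid_sim_spec(noise_sd = 0, t_max = 1200, dt = 8)
  traces <- generate_fid_series(truth, sim)
  dir <- withr::local_tempdir()
  files <- vapply(seq_along(traces), function(i) {
    f <- file.path(dir, sprintf("fid_%02d.csv", i))
    write_fid(traces[[i]], f)
    basename(f)
  }, "")
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(file = files), manifest, row.names = FALSE,
                   quote = FALSE)
  md <- from_fid_series(manifest, config = list(total_reference = 1))
  expect_equal(nrow(md), 12L)
  expect_lt(max(abs(md$n - truth_curve(truth))), 1e-4)

  # fault injection: one corrupt file among the set is excluded with warning
  writeLines("not an fid", file.path(dir, files[3]))
  expect_warning(md_f <- from_fid_series(manifest,
                                         config = list(total_reference = 1)),
                 class = "hydromelt_excluded_traces")
  expect_equal(nrow(md_f), 11L)

  # empty manifest is an error
  empty <- file.path(dir, "empty.csv")
  utils::write.csv(data.frame(file = character()), empty, row.names = FALSE)
  expect_error(from_fid_series(empty, config = list(total_reference = 1)),
               class = "hydromelt_invalid_input")
  expect_error(from_fid_series(manifest, config = list()),
               class = "hydromelt_invalid_input")
})

test_that("sample specifications validate their fields", {
  sp <- sample_spec("X", 50, 10000, 100)
  expect_equal(sp$water_molarity, 55.35)
  expect_error(sample_spec("X", -1, 10000, 100),
               class = "hydromelt_invalid_input")
  expect_error(sample_spec("X", 50, 10000, 10.5),
               class = "hydromelt_invalid_input")
  sp2 <- sample_spec("X", 50, 10000, 100, water_mass_fraction = 0.95)
  expect_equal(sp2$water_molarity, 950 / 18.015, tolerance = 1e-6)
  path <- withr::local_tempfile(fileext = ".json")
  write_sample_spec(sp, path)
  sp3 <- read_sample_spec(path)
  expect_equal(sp3$molecular_weight, sp$molecular_weight)
  expect_equal(sp3$residue_count, sp$residue_count)
})
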