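test_that("config validation rejects malformed settings", {
  expect_error(qc_config(bogus = 1), "unknown")
  expect_error(qc_config(t_bc = -1), "positive")
  expect_error(qc_config(wv_range = c(2, 1)), "interval")
  expect_error(qc_config(wv_peak_max = 100), "inside wv_range")
  cfg <- qc_config(t_bc = 1e-4)
  expect_equal(cfg$t_bc, 1e-4)
})

test_that("config round-trips through YAML with defaults for absent fields", {
  p <- tempfile(fileext = ".yml")
  yaml::write_yaml(list(savgol_window = 31, noise_range = c(2600, 2650)), p)
  cfg <- read_qc_config(p)
  expect_equal(cfg$savgol_window, 31)
  expect_equal(cfg$noise_range, c(2600, 2650))
  expect_equal(cfg$t_bc, qc_config()$t_bc)
})

test_that("baseline diagnostic separates corrected from uncorrected spectra", {
  cfg <- qc_config()
  s <- rubberband(noisy_spectrum(seed = 41))
  d <- baseline_diagnostic(s, cfg)
  expect_true(d$is_baseline_corrected)
  expect_lte(d$i1400, cfg$t_bc)
  # add a convex decaying baseline: the hull picks it up at 1400 cm^-1
  s2 <- with_intensity_test(s, s$intensity + 0.4 * exp(-s$wavenumber / 1000))
  d2 <- baseline_diagnostic(s2, cfg)
  expect_false(d2$is_baseline_corrected)
  expect_gt(d2$i1400, 2 * cfg$t_bc)
})

test_that("the OLS slope helper matches lm and is exact on self-fits", {
  set.seed(51)
  x <- runif(80)
  y <- 0.3 + 1.7 * x + rnorm(80, 0, 0.05)
  mine <- mirqc:::ols_slope(y, x)
  fit <- summary(stats::lm(y ~ x))$coefficients
  expect_equal(mine$estimate, fit[2, 1], tolerance = 1e-12)
  expect_equal(mine$se, fit[2, 2], tolerance = 1e-12)
  self <- mirqc:::ols_slope(x, x)
  expect_identical(self$estimate, 1)
  expect_identical(self$se, 0)
})

test_that("artifact contribution is calibrated, linear and sign-preserving", {
  cfg <- qc_config()
  refs <- test_refs()
  s <- clean_spectrum(seed = 42)
  # alpha = 0.5 recovery for the generic operation
  got <- artifact_contribution(inject_artifact(s, refs$water_vapor, 0.5, cfg),
                               refs$water_vapor, cfg$wv_range,
                               cfg$wv_peak_max, cfg)
  expect_equal(got$estimate, 0.5, tolerance = 0.02)
  # zero query region -> slope 0
  wn <- s$wavenumber
  z <- mir_spectrum(wn, ifelse(wn >= 3700, 0, s$intensity))
  expect_equal(water_vapor_contribution(z, refs$water_vapor, cfg)$estimate, 0)
  # linearity: c grows one-to-one with the injected scale
  alphas <- c(0.25, 0.5, 1, 2)
  cs <- vapply(alphas, function(a) {
    water_vapor_contribution(inject_artifact(s, refs$water_vapor, a, cfg),
                             refs$water_vapor, cfg)$estimate
  }, numeric(1))
  expect_true(all(diff(cs) > 0))
  expect_equal(unname(coef(lm(cs ~ alphas))[2]), 1, tolerance = 0.05)
  # negative artifacts keep their sign: CO2 exactly (its region is excised
  # from the area normalizer), water vapor at an attainable magnitude
  nc <- co2_contribution(inject_artifact(s, refs$co2, -0.3, cfg),
                         refs$co2, cfg)
  expect_equal(nc$estimate, -0.3, tolerance = 0.02)
  nw <- water_vapor_contribution(inject_artifact(s, refs$water_vapor, -0.05,
                                                 cfg),
                                 refs$water_vapor, cfg)
  expect_equal(nw$estimate, -0.05, tolerance = 0.02)
})

test_that("spectra without region coverage are flagged, not failed", {
  cfg <- qc_config()
  refs <- test_refs()
  atr <- clip_spectrum(clean_spectrum(), c(650, 3750))
  got <- water_vapor_contribution(atr, refs$water_vapor, cfg)
  expect_true(is.na(got$estimate))
  expect_match(got$flag, "missing coverage")
})

test_that("null spectra give near-zero artifact estimates", {
  cfg <- qc_config()
  refs <- test_refs()
  cs <- vapply(1:40, function(i) {
    s <- noisy_spectrum(seed = 600 + i)
    co2_contribution(s, refs$co2, cfg)$estimate
  }, numeric(1))
  # unbiased around zero and small relative to any real contribution
  expect_lt(abs(mean(cs)), 5 * sd(cs) / sqrt(length(cs)))
  expect_lt(max(abs(cs)), 5e-3)
})

test_that("noise level is sensitive, scale-free and baseline-free", {
  cfg <- qc_config()
  smooth <- clean_spectrum(seed = 43)
  expect_lt(noise_level(smooth, cfg), 1e-12)
  # strictly increasing mean across the noise grid
  grid <- c(1e-4, 3e-4, 1e-3)
  means <- vapply(grid, function(sd) {
    mean(vapply(1:50, function(i) {
      noise_level(noisy_spectrum(seed = 700 + i, noise_sd = sd), cfg)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  # invariances
  s <- noisy_spectrum(seed = 44)
  v0 <- noise_level(s, cfg)
  expect_equal(noise_level(with_intensity_test(s, 2 * s$intensity), cfg), v0,
               tolerance = 1e-10)
  aff <- with_intensity_test(s, s$intensity + 0.5 - 1e-4 * s$wavenumber)
  expect_equal(noise_level(aff, cfg), v0, tolerance = 1e-8 * v0 + 1e-8)
})

test_that("the QC report has the stored metadata column layout", {
  cfg <- qc_config()
  refs <- test_refs()
  batch <- mir_batch(lapply(1:3, function(i) noisy_spectrum(seed = 800 + i)))
  rep <- qc_report(batch, refs, cfg)
  expect_identical(nrow(rep), 3L)
  expect_identical(
    names(rep),
    c("id", "is_baseline_corrected",
      "mir_water_vapor_contribution_relative",
      "mir_water_vapor_contribution_relative_sd",
      "mir_co2_contribution_relative", "mir_co2_contribution_relative_sd",
      "noise_level_relative", "i1400", "total_area", "flags"))
  # a spectrum without wv coverage yields an empty cell plus a flag
  atr <- clip_spectrum(noisy_spectrum(seed = 804), c(650, 3750))
  rep2 <- qc_report(mir_batch(list(atr)), refs, cfg)
  expect_true(is.na(rep2$mir_water_vapor_contribution_relative))
  expect_match(rep2$flags, "coverage")
  # written report renders NA as empty cell
  p <- tempfile(fileext = ".csv")
  write_qc_report(rep2, p)
  line2 <- readLines(p)[2]
  expect_match(line2, ",,")
})
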