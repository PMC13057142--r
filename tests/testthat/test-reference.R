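test_that("identical or structureless background pairs are rejected", {
  wn <- 400:4000
  env <- mir_spectrum(wn, 0.1 + 0.8 * exp(-((wn - 1900) / 1700)^2),
                      mode = "transmission")
  pair <- background_pair(env, env)
  expect_error(derive_co2_reference(pair), "degenerate")
  # no gas structure, only a throughput offset: degenerate after correction
  flat <- simulate_background_pair(seed = 1, wv_delta = 0, co2_delta = 0,
                                   noise_sd = 0)
  expect_error(derive_co2_reference(flat), "degenerate")
})

test_that("CO2 derivation recovers a known injected doublet", {
  pair <- simulate_background_pair(seed = 31, wv_delta = 0, co2_delta = 0.06,
                                   noise_sd = 0)
  ref <- derive_co2_reference(pair)
  expect_identical(ref$species, "co2")
  truth <- clip_spectrum(make_artifact_comb("co2"), c(2250, 2450))
  got <- clip_spectrum(ref$spectrum, c(2250, 2450))
  expect_gt(cor(truth$intensity, got$intensity), 0.99)
  # replaced regions are straight lines (zero second differences)
  sd2 <- function(s, rng) {
    y <- s$intensity[s$wavenumber >= rng[1] & s$wavenumber <= rng[2]]
    max(abs(diff(diff(y))))
  }
  expect_lt(sd2(ref$spectrum, c(729, 2229)), 1e-10)
  expect_lt(sd2(ref$spectrum, c(3801, 4000)), 1e-10)
})

test_that("CO2 derivation cancels any shared smooth throughput factor", {
  pair <- simulate_background_pair(seed = 32, wv_delta = 0, co2_delta = 0.05,
                                   noise_sd = 0)
  ref1 <- derive_co2_reference(pair)
  wn <- pair$bg_a$wavenumber
  f <- 0.6 + 0.3 * sin(wn / 900)
  pair2 <- background_pair(
    mir_spectrum(wn, pair$bg_a$intensity * f, mode = "transmission"),
    mir_spectrum(wn, pair$bg_b$intensity * f, mode = "transmission"))
  ref2 <- derive_co2_reference(pair2)
  expect_equal(ref2$spectrum$intensity, ref1$spectrum$intensity,
               tolerance = 1e-8)
})

test_that("swapping the background scans negates the absorbance ratio", {
  pair <- simulate_background_pair(seed = 33)
  swapped <- background_pair(pair$bg_b, pair$bg_a)
  a1 <- mirqc:::background_ratio_absorbance(pair)
  a2 <- mirqc:::background_ratio_absorbance(swapped)
  expect_equal(a2$intensity, -a1$intensity, tolerance = 1e-10)
})

test_that("atmospheric correction recovers and removes the gas scale", {
  refs <- test_refs()
  ref <- refs$co2
  wn <- ref$spectrum$wavenumber
  # s = 2 * ref -> residual ~ 0
  s2 <- mir_spectrum(wn, 2 * ref$spectrum$intensity)
  out <- atmospheric_correct(s2, ref)
  expect_lt(max(abs(out$intensity)), 1e-8)
  # s = clean + 0.7 * ref -> slope 0.7 recovered (residual lacks the doublet)
  clean <- 0.05 + 1e-5 * wn
  s3 <- mir_spectrum(wn, clean + 0.7 * ref$spectrum$intensity)
  out3 <- atmospheric_correct(s3, ref)
  expect_equal(max(abs(out3$intensity - clean)), 0, tolerance = 0.02 * 0.7)
  # no gas signature -> spectrum unchanged within noise
  set.seed(8)
  noise <- rnorm(length(wn), 0, 1e-4)
  s4 <- mir_spectrum(wn, clean + noise)
  out4 <- atmospheric_correct(s4, ref)
  expect_lt(max(abs(out4$intensity - s4$intensity)), 5e-4)
})

test_that("water-vapor derivation closes the loop on a known comb", {
  refs <- test_refs()
  ref <- refs$water_vapor
  expect_identical(ref$species, "water_vapor")
  expect_identical(intensity_at(ref$spectrum, 2000), 0)
  expect_gte(min(ref$spectrum$intensity), 0)
  truth <- clip_spectrum(make_artifact_comb("water_vapor"), c(3780, 3920))
  got <- clip_spectrum(ref$spectrum, c(3780, 3920))
  expect_gt(cor(truth$intensity, got$intensity), 0.99)
  sd2 <- function(s, rng) {
    y <- s$intensity[s$wavenumber >= rng[1] & s$wavenumber <= rng[2]]
    max(abs(diff(diff(y))))
  }
  expect_lt(sd2(ref$spectrum, c(601, 1199)), 1e-10)
  expect_lt(sd2(ref$spectrum, c(2201, 3299)), 1e-10)
})

test_that("the anchor at 2000 cm^-1 must be positive", {
  # swapped drift direction: bg_a brighter than bg_b -> negative offset
  pair <- simulate_background_pair(seed = 34, wv_delta = 0.03,
                                   co2_delta = 0.01, noise_sd = 0)
  swapped <- background_pair(pair$bg_b, pair$bg_a)
  expect_error(derive_water_vapor_reference(swapped, test_refs()$co2),
               "anchor")
})

test_that("gas deltas control which species can be derived", {
  co2_only <- simulate_background_pair(seed = 35, wv_delta = 0,
                                       co2_delta = 0.05)
  wv_only <- simulate_background_pair(seed = 36, wv_delta = 0.03,
                                      co2_delta = 0)
  ref_c <- derive_co2_reference(co2_only)
  truth_c <- clip_spectrum(make_artifact_comb("co2"), c(2250, 2450))
  expect_gt(cor(truth_c$intensity,
                clip_spectrum(ref_c$spectrum, c(2250, 2450))$intensity), 0.99)
  # deriving water vapor from the co2-only pair finds no comb
  wv_from_co2 <- derive_water_vapor_reference(co2_only, ref_c)
  truth_w <- clip_spectrum(make_artifact_comb("water_vapor"), c(3780, 3920))
  expect_lt(cor(truth_w$intensity,
                clip_spectrum(wv_from_co2$spectrum,
                              c(3780, 3920))$intensity + 0), 0.5)
  # and the wv-only pair yields a clean water-vapor reference
  ref_w <- derive_water_vapor_reference(wv_only, ref_c)
  expect_gt(cor(truth_w$intensity,
                clip_spectrum(ref_w$spectrum, c(3780, 3920))$intensity), 0.99)
})

test_that("references persist as CSV plus provenance sidecar", {
  ref <- test_refs()$co2
  p <- file.path(tempdir(), "co2.csv")
  write_reference(ref, p)
  back <- read_reference(p)
  expect_identical(back$species, "co2")
  expect_equal(back$spectrum$intensity, ref$spectrum$intensity,
               tolerance = 1e-9)
  expect_identical(back$provenance, ref$provenance)
})

test_that("device lookup resolves entries and falls back with a warning", {
  d <- tempdir()
  write_reference(test_refs()$co2, file.path(d, "lk_co2.csv"))
  write_reference(test_refs()$water_vapor, file.path(d, "lk_wv.csv"))
  lk <- file.path(d, "lookup.yml")
  yaml::write_yaml(list(
    "Bruker Vector 22" = list(water_vapor = "lk_wv.csv", co2 = "lk_co2.csv"),
    default = list(water_vapor = "lk_wv.csv", co2 = "lk_co2.csv")), lk)
  lookup <- read_reference_lookup(lk)
  refs <- refs_for_device(lookup, "Bruker Vector 22", base = d)
  expect_identical(refs$co2$species, "co2")
  expect_warning(refs_for_device(lookup, "no-such-device", base = d),
                 "falling back")
})
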