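# Shared fixtures, built in code and cached for the test session.

.fixture_env <- new.env(parent = emptyenv())

# reference pair derived once from simulated background scans:
# a CO2-dominated pair and a water-vapor-dominated pair
test_refs <- function() {
  if (is.null(.fixture_env$refs)) {
    ref_co2 <- derive_co2_reference(
      simulate_background_pair(seed = 11, wv_delta = 0.004, co2_delta = 0.05))
    ref_wv <- derive_water_vapor_reference(
      simulate_background_pair(seed = 12, wv_delta = 0.03, co2_delta = 0.01),
      ref_co2)
    .fixture_env$refs <- list(water_vapor = ref_wv, co2 = ref_co2)
  }
  .fixture_env$refs
}

clean_spectrum <- function(seed = 1L) {
  simulate_spectrum(artifact_truth(noise_sd = 0, seed = seed),
                    id = paste0("clean_", seed))$spectrum
}

noisy_spectrum <- function(seed = 1L, noise_sd = 1e-3) {
  simulate_spectrum(artifact_truth(noise_sd = noise_sd, seed = seed),
                    id = paste0("noisy_", seed))$spectrum
}

with_intensity_test <- function(s, y) {
  mir_spectrum(s$wavenumber, y, mode = s$mode, id = s$id)
}

with_seed_test <- function(seed, code) mirqc:::with_seed(seed, code)

# Brute-force lower convex envelope oracle, independent of the package's
# monotone-chain implementation: the envelope is the pointwise maximum over
# all chords between data-point pairs that lie at or below every data point.
# O(n^3); only for small fixtures.
brute_lower_envelope <- function(wn, y) {
  n <- length(wn)
  env <- rep(-Inf, n)
  for (j in 1:(n - 1)) {
    for (k in (j + 1):n) {
      b <- (y[k] - y[j]) / (wn[k] - wn[j])
      line <- y[j] + b * (wn - wn[j])
      if (all(y >= line - 1e-10)) env <- pmax(env, line)
    }
  }
  env
}
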