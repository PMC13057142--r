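# Evaluate code with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

gauss <- function(x, center, sd, height) height * exp(-(x - center)^2 / (2 * sd^2))

#' Default organic-matter band set
#'
#' Gaussian band parameters emulating a typical organic-matter (peat)
#' absorbance spectrum: a strong, broad O-H/N-H stretch (3400 cm^-1,
#' comparable in height to the polysaccharide band, as in real peat
#' spectra), aliphatic C-H stretches (2920, 2850), carbonyl (1720),
#' aromatic C=C / carboxylate (1630), aromatic skeletal (1510), C-H
#' deformation (1420) and polysaccharide C-O (1090).
#'
#' @return Data frame with columns `center`, `width` (Gaussian sd, cm^-1)
#'   and `height` (relative absorbance).
#' @export
default_om_peaks <- function() {
  data.frame(
    center = c(3400, 2920, 2850, 1720, 1630, 1510, 1420, 1090),
    width  = c( 170,   28,   24,   42,   45,   30,   38,   60),
    height = c(0.80, 0.22, 0.15, 0.38, 0.52, 0.22, 0.30, 0.70)
  )
}

#' Ground truth for a synthetic spectrum
#'
#' @param peaks Data frame `center`/`width`/`height` of Gaussian bands.
#' @param baseline List with `offset`, `slope` (per cm^-1), `decay_amp` and
#'   `decay_rate` (cm^-1) describing an additive baseline
#'   `offset + slope * nu + decay_amp * exp(-nu / decay_rate)`.
#' @param wv_scale,co2_scale Scale factors applied to the raw water-vapor /
#'   CO2 artifact combs added to the spectrum.
#' @param noise_sd Standard deviation of iid Gaussian intensity noise
#'   (absorbance units). The default, 1e-3, is a typical noise floor for a
#'   transmission FTIR scan of this intensity scale.
#' @param seed Integer seed; recorded in the output metadata.
#' @param intensity_scale Multiplier applied to the band sum; the default
#'   0.163 gives a total baseline-corrected area near 100 for the default
#'   band set.
#' @return A list of class `artifact_truth`.
#' @export
artifact_truth <- function(peaks = default_om_peaks(),
                           baseline = list(offset = 0, slope = 0,
                                           decay_amp = 0, decay_rate = 1000),
                           wv_scale = 0, co2_scale = 0, noise_sd = 1e-3,
                           seed = 1L, intensity_scale = 0.163) {
  stopifnot(all(c("center", "width", "height") %in% names(peaks)),
            all(peaks$width > 0), noise_sd >= 0)
  base <- list(offset = 0, slope = 0, decay_amp = 0, decay_rate = 1000)
  base[names(baseline)] <- baseline
  structure(list(peaks = peaks, baseline = base, wv_scale = wv_scale,
                 co2_scale = co2_scale, noise_sd = noise_sd,
                 seed = as.integer(seed), intensity_scale = intensity_scale),
            class = "artifact_truth")
}

# deterministic line lists for the artifact combs
wv_comb_lines <- function() {
  p1 <- seq(1350, 1900, by = 25)
  h1 <- rep(c(0.45, 0.75), length.out = length(p1))
  p2 <- seq(3500, 3820, by = 24)
  h2 <- rep(c(0.35, 0.60), length.out = length(p2))
  p3 <- c(3853, 3880, 3906)
  h3 <- c(1.00, 0.50, 0.40)
  data.frame(center = c(p1, p2, p3), height = c(h1, h2, h3), width = 2)
}

co2_comb_lines <- function() {
  data.frame(center = c(668, 2340, 2362), height = c(0.55, 0.85, 1.00),
             width = c(8, 7, 7))
}

#' Synthetic atmospheric artifact comb
#'
#' Deterministic, nonnegative spectra with unit maximum that mimic the shape
#' of residual atmospheric absorption. Water vapor: narrow (sd 2 cm^-1)
#' rotational-vibrational lines of alternating height spanning 1300-1900 and
#' 3500-3920 cm^-1, with the global maximum at 3853 cm^-1. CO2: the
#' asymmetric-stretch doublet near 2340/2362 cm^-1 plus the bending band
#' near 668 cm^-1.
#'
#' @param species `"water_vapor"` or `"co2"`.
#' @param wavenumber Wavenumber grid (cm^-1) to evaluate on.
#' @return A [mir_spectrum] in absorbance mode.
#' @export
make_artifact_comb <- function(species = c("water_vapor", "co2"),
                               wavenumber = 400:4000) {
  species <- match.arg(species)
  lines <- if (species == "water_vapor") wv_comb_lines() else co2_comb_lines()
  y <- rep(0, length(wavenumber))
  for (i in seq_len(nrow(lines))) {
    y <- y + gauss(wavenumber, lines$center[i], lines$width[i],
                   lines$height[i])
  }
  m <- max(y)
  if (m > 0) y <- y / m
  mir_spectrum(wavenumber, y, mode = "absorbance",
               id = paste0(species, "_comb"))
}

#' Simulate an organic-matter spectrum with known ground truth
#'
#' The spectrum is the sum of the Gaussian organic bands, the additive
#' baseline, the scaled water-vapor and CO2 artifact combs, and iid Gaussian
#' noise, generated reproducibly from `truth$seed` without touching the
#' global RNG state.
#'
#' @param truth An [artifact_truth].
#' @param range Wavenumber range to cover (default `c(650, 3999)`).
#' @param dw Grid spacing (default 1 cm^-1).
#' @param id Spectrum id.
#' @return A list with elements `spectrum` ([mir_spectrum]) and `truth`.
#' @export
simulate_spectrum <- function(truth = artifact_truth(),
                              range = c(650, 3999), dw = 1,
                              id = "synthetic") {
  stopifnot(inherits(truth, "artifact_truth"))
  if (diff(range) < 10 * dw) stop("grid range too short", call. = FALSE)
  wn <- seq(range[1], range[2], by = dw)
  y <- rep(0, length(wn))
  for (i in seq_len(nrow(truth$peaks))) {
    y <- y + gauss(wn, truth$peaks$center[i], truth$peaks$width[i],
                   truth$peaks$height[i])
  }
  y <- y * truth$intensity_scale
  b <- truth$baseline
  y <- y + b$offset + b$slope * wn + b$decay_amp * exp(-wn / b$decay_rate)
  if (truth$wv_scale != 0) {
    y <- y + truth$wv_scale * make_artifact_comb("water_vapor", wn)$intensity
  }
  if (truth$co2_scale != 0) {
    y <- y + truth$co2_scale * make_artifact_comb("co2", wn)$intensity
  }
  if (truth$noise_sd > 0) {
    y <- y + with_seed(truth$seed, stats::rnorm(length(wn), 0, truth$noise_sd))
  }
  s <- mir_spectrum(wn, y, mode = "absorbance", id = id,
                    metadata = list(seed = truth$seed))
  list(spectrum = s, truth = truth)
}

#' Simulate a pair of background scans
#'
#' `bg_b` is a smooth source-emission envelope in transmission; `bg_a` is
#' the same envelope attenuated by atmospheric gas absorption
#' (`10^-(drift + wv_delta * wv_comb + co2_delta * co2_comb)`), i.e. the
#' scan recorded with the higher gas concentration, plus a small broadband
#' throughput drift between the two scans. Independent iid noise is added to
#' both scans. Everything is reproducible from `seed`.
#'
#' @param seed Integer seed.
#' @param wv_delta,co2_delta Absorbance-scale differences in water-vapor /
#'   CO2 concentration between the scans (defaults 0.02 and 0.05: small
#'   atmospheric differences typical between purge states).
#' @param drift Broadband absorbance offset between the scans (default
#'   0.012, emulating source/throughput drift).
#' @param noise_sd Transmission noise standard deviation (default 1e-4).
#' @param range Wavenumber range (default `c(400, 4000)`).
#' @return A [background_pair].
#' @export
simulate_background_pair <- function(seed = 1L, wv_delta = 0.02,
                                     co2_delta = 0.05, drift = 0.012,
                                     noise_sd = 1e-4, range = c(400, 4000)) {
  stopifnot(wv_delta >= 0, co2_delta >= 0)
  wn <- seq(range[1], range[2], by = 1)
  env <- 0.10 + 0.82 * exp(-((wn - 1900) / 1700)^2)
  absn <- drift +
    wv_delta * make_artifact_comb("water_vapor", wn)$intensity +
    co2_delta * make_artifact_comb("co2", wn)$intensity
  noise <- with_seed(seed, matrix(stats::rnorm(2L * length(wn), 0, noise_sd),
                                  ncol = 2L))
  a <- pmax(env * 10^(-absn) + noise[, 1L], 1e-6)
  b <- pmax(env + noise[, 2L], 1e-6)
  background_pair(
    mir_spectrum(wn, a, mode = "transmission", id = "bg_a",
                 metadata = list(seed = seed)),
    mir_spectrum(wn, b, mode = "transmission", id = "bg_b",
                 metadata = list(seed = seed)),
    device = "synthetic"
  )
}

#' Inject a gas artifact of known relative contribution
#'
#' Adds a scaled copy of the processed reference region (the reference passed
#' through [extract_peak] and divided by its own total area, exactly as the
#' estimator processes it) to the spectrum, calibrated so that the relative
#' contribution measured by [artifact_contribution] on the modified spectrum
#' equals `alpha`. Because the injected intensity itself enlarges the total
#' area for regions outside the CO2 interpolation range, the raw injection
#' scale is solved by a short fixed-point iteration on the actual total
#' area.
#'
#' @param s Clean [mir_spectrum] covering the region and area range.
#' @param ref A `mir_reference`.
#' @param alpha Target relative contribution (may be negative).
#' @param cfg A [qc_config].
#' @return The spectrum with the injected artifact.
#' @export
inject_artifact <- function(s, ref, alpha, cfg = qc_config()) {
  stopifnot(is_mir_spectrum(s), inherits(ref, "mir_reference"))
  rng <- if (ref$species == "water_vapor") cfg$wv_range else cfg$co2_range
  pk <- if (ref$species == "water_vapor") cfg$wv_peak_max else cfg$co2_peak_max
  pr <- extract_peak(ref$spectrum, rng, pk)
  pr <- with_intensity(pr, pr$intensity / total_area(ref$spectrum, cfg))
  idx <- match(pr$wavenumber, s$wavenumber)
  if (anyNA(idx)) {
    stop("spectrum grid does not contain the artifact region grid",
         call. = FALSE)
  }
  a0 <- total_area(s, cfg)
  beta <- alpha
  for (k in seq_len(60L)) {
    y <- s$intensity
    y[idx] <- y[idx] + beta * a0 * pr$intensity
    anew <- total_area(with_intensity(s, y), cfg)
    beta_next <- alpha * anew / a0
    done <- abs(beta_next - beta) < 1e-9 * max(1, abs(beta))
    beta <- beta_next
    if (done) break
  }
  if (!done) {
    stop(sprintf(paste0("artifact scale %g is not attainable: the injected ",
                        "artifact inflates the total-area normalizer faster ",
                        "than the regression signal grows"), alpha),
         call. = FALSE)
  }
  y <- s$intensity
  y[idx] <- y[idx] + beta * a0 * pr$intensity
  with_intensity(s, y)
}

#' Simulate a panel of spectra with known artifact contributions
#'
#' Generates `n` organic-matter spectra with jittered band heights, injects
#' water-vapor and CO2 artifacts of known relative contribution drawn from
#' the given ranges, and adds measurement noise. Used to validate the
#' end-to-end quality-control pipeline.
#'
#' @param n Number of spectra.
#' @param refs List with `water_vapor` and `co2` `mir_reference` entries.
#' @param seed Integer seed.
#' @param alpha_wv,alpha_co2 Length-2 ranges from which the true relative
#'   contributions are drawn uniformly.
#' @param noise_sd Intensity noise standard deviation.
#' @param cfg A [qc_config].
#' @return A list with `batch` ([mir_batch]) and `truth` (data frame with
#'   columns `id`, `alpha_wv`, `alpha_co2`, `noise_sd`, `seed`).
#' @export
simulate_qc_panel <- function(n, refs, seed = 1L, alpha_wv = c(0, 1),
                              alpha_co2 = c(0, 1), noise_sd = 1e-3,
                              cfg = qc_config()) {
  draws <- with_seed(seed, list(
    jitter = matrix(stats::runif(n * 8L, 0.85, 1.15), nrow = n),
    a_wv = stats::runif(n, alpha_wv[1], alpha_wv[2]),
    a_co2 = stats::runif(n, alpha_co2[1], alpha_co2[2]),
    seeds = sample.int(.Machine$integer.max - 1L, n)
  ))
  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    pk <- default_om_peaks()
    pk$height <- pk$height * draws$jitter[i, ]
    tr <- artifact_truth(peaks = pk, noise_sd = noise_sd,
                         seed = draws$seeds[i])
    s <- simulate_spectrum(tr, id = sprintf("syn_%04d", i))$spectrum
    # inject into the noisy spectrum: the injection scale is calibrated
    # against the same total-area normalizer the estimator will use
    s <- inject_artifact(s, refs$water_vapor, draws$a_wv[i], cfg)
    s <- inject_artifact(s, refs$co2, draws$a_co2[i], cfg)
    spectra[[i]] <- s
  }
  list(batch = mir_batch(spectra),
       truth = data.frame(id = batch_ids(mir_batch(spectra)),
                          alpha_wv = draws$a_wv, alpha_co2 = draws$a_co2,
                          noise_sd = noise_sd, seed = draws$seeds))
}
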