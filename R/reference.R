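#' Pair of instrument background scans
#'
#' Two single-beam background scans recorded on the same device (ideally the
#' same day) under different atmospheric gas concentrations, both stored as
#' transmission. Their ratio isolates the change in atmospheric absorption
#' between the two scans, which is the raw material for a pure-gas reference
#' spectrum.
#'
#' @param bg_a,bg_b [mir_spectrum] objects in transmission mode. `bg_a` is
#'   the scan with the higher gas concentration, so that the absorbance of
#'   `bg_a / bg_b` shows positive gas lines.
#' @param device Device label.
#' @param recorded_on Optional date string.
#' @return An object of class `background_pair`.
#' @export
background_pair <- function(bg_a, bg_b, device = "unknown",
                            recorded_on = NULL) {
  stopifnot(is_mir_spectrum(bg_a), is_mir_spectrum(bg_b))
  if (bg_a$mode != "transmission" || bg_b$mode != "transmission") {
    stop("background scans must be in transmission mode", call. = FALSE)
  }
  structure(list(bg_a = bg_a, bg_b = bg_b, device = device,
                 recorded_on = recorded_on),
            class = "background_pair")
}

#' @export
print.background_pair <- function(x, ...) {
  cat(sprintf("<background_pair> device %s: %d / %d points\n", x$device,
              length(x$bg_a$wavenumber), length(x$bg_b$wavenumber)))
  invisible(x)
}

new_reference <- function(spectrum, species, device, provenance) {
  structure(list(spectrum = spectrum, species = species, device = device,
                 provenance = provenance),
            class = "mir_reference")
}

#' @export
print.mir_reference <- function(x, ...) {
  cat(sprintf("<mir_reference> %s (device %s), %d points\n", x$species,
              x$device, length(x$spectrum$wavenumber)))
  invisible(x)
}

# ratio of the two backgrounds on a shared dw=1 grid, as absorbance
background_ratio_absorbance <- function(pair, dw = 1) {
  a <- interpolate_to_grid(pair$bg_a, dw = dw)
  b <- interpolate_to_grid(pair$bg_b, dw = dw)
  lo <- max(min(a$wavenumber), min(b$wavenumber))
  hi <- min(max(a$wavenumber), max(b$wavenumber))
  if (hi - lo < 2) stop("backgrounds do not overlap", call. = FALSE)
  a <- clip_spectrum(a, c(lo, hi))
  b <- clip_spectrum(b, c(lo, hi))
  ratio <- mir_spectrum(a$wavenumber, a$intensity / pmax(b$intensity, 1e-12),
                        mode = "ratio", id = paste0(pair$device, "_ratio"))
  to_absorbance(ratio)
}

# straight-line replacement of the > nu_from tail: the grid point nearest
# nu_from (from above) and the final grid point are the anchors
replace_tail_linear <- function(s, nu_from) {
  n <- length(s$wavenumber)
  i0 <- which(s$wavenumber >= nu_from)[1L]
  if (is.na(i0) || i0 >= n - 1L) return(s)
  y <- s$intensity
  idx <- i0:n
  y[idx] <- stats::approx(s$wavenumber[c(i0, n)], y[c(i0, n)],
                          xout = s$wavenumber[idx])$y
  with_intensity(s, y)
}

#' Derive a pure CO2 reference spectrum from a background pair
#'
#' The two background scans are divided, the ratio converted to absorbance,
#' interpolated to an integer (1 cm^-1) grid, the regions 728-2230 cm^-1 and
#' above 3800 cm^-1 (which contain no CO2 bands) are replaced by straight
#' lines to remove residual noise and water-vapor lines, and a rubberband
#' baseline correction is applied.
#'
#' @param pair A [background_pair].
#' @return A `mir_reference` with `species = "co2"`.
#' @export
derive_co2_reference <- function(pair) {
  stopifnot(inherits(pair, "background_pair"))
  a <- background_ratio_absorbance(pair)
  if (max(abs(a$intensity)) < 1e-6) {
    stop("degenerate reference: backgrounds are near-identical", call. = FALSE)
  }
  a <- replace_region_linear(a, c(728, 2230))
  a <- replace_tail_linear(a, 3800)
  a <- rubberband(a)
  if (max(abs(a$intensity)) < 1e-6) {
    stop("degenerate reference: no gas structure after baseline correction",
         call. = FALSE)
  }
  a$id <- paste0(pair$device, "_co2_reference")
  new_reference(a, "co2", pair$device,
                c("ratio bg_a/bg_b", "to_absorbance",
                  "interpolate dw=1", "replace_region_linear 728-2230",
                  "replace_tail_linear >3800", "rubberband"))
}

#' Atmospheric correction against a gas reference spectrum
#'
#' Fits the spectrum's intensities on the reference intensities within
#' `fit_range` by ordinary least squares (with intercept) and subtracts
#' `slope * reference` over the full shared grid, removing the scaled gas
#' signature.
#'
#' @param s A [mir_spectrum] (absorbance).
#' @param ref A `mir_reference` covering `s`'s grid and `fit_range`.
#' @param fit_range Interval (cm^-1) used to estimate the scale factor.
#' @return The corrected [mir_spectrum].
#' @export
atmospheric_correct <- function(s, ref, fit_range = c(2250, 2450)) {
  stopifnot(is_mir_spectrum(s), inherits(ref, "mir_reference"))
  if (!covers_range(s, fit_range) || !covers_range(ref$spectrum, fit_range)) {
    stop("spectrum and reference must both cover the fit range", call. = FALSE)
  }
  rs <- clip_spectrum(s, fit_range)
  rr <- clip_spectrum(ref$spectrum, fit_range)
  rv <- stats::approx(rr$wavenumber, rr$intensity, xout = rs$wavenumber)$y
  if (stats::var(rv) == 0) {
    stop("reference has zero variance in the fit range", call. = FALSE)
  }
  slope <- unname(stats::coef(stats::lm(rs$intensity ~ rv))[2L])
  rfull <- stats::approx(ref$spectrum$wavenumber, ref$spectrum$intensity,
                         xout = s$wavenumber, rule = 2)$y
  with_intensity(s, s$intensity - slope * rfull)
}

#' Derive a pure water-vapor reference spectrum from a background pair
#'
#' As for CO2 the scans are divided, converted to absorbance and interpolated
#' to a 1 cm^-1 grid, but no regions are replaced at this stage. An
#' atmospheric correction with the supplied CO2 reference removes residual
#' CO2 (the scans rarely share exactly the same CO2 concentration). Remaining
#' negative values are removed by dividing the intensities so that the value
#' at 2000 cm^-1 (a broadband offset level free of gas lines) is 1,
#' subtracting 1, and clamping negatives to 0. Finally the regions 600-1200
#' and 2200-3300 cm^-1, which contain no sharp water-vapor lines, are
#' replaced by straight lines.
#'
#' @param pair A [background_pair].
#' @param co2_ref A CO2 `mir_reference` used for the atmospheric correction.
#' @return A `mir_reference` with `species = "water_vapor"`; its value at
#'   2000 cm^-1 is 0 and all intensities are nonnegative.
#' @export
derive_water_vapor_reference <- function(pair, co2_ref) {
  stopifnot(inherits(pair, "background_pair"))
  if (!inherits(co2_ref, "mir_reference") || co2_ref$species != "co2") {
    stop("co2_ref must be a CO2 reference spectrum", call. = FALSE)
  }
  a <- background_ratio_absorbance(pair)
  if (max(abs(a$intensity)) < 1e-6) {
    stop("degenerate reference: backgrounds are near-identical", call. = FALSE)
  }
  a <- atmospheric_correct(a, co2_ref, fit_range = c(2250, 2450))
  anchor <- intensity_at(a, 2000)
  if (!is.finite(anchor) || anchor <= 0) {
    stop("anchor error: absorbance at 2000 cm^-1 must be positive",
         call. = FALSE)
  }
  y <- a$intensity / anchor - 1
  y[y < 0] <- 0
  a <- with_intensity(a, y)
  a <- replace_region_linear(a, c(600, 1200))
  a <- replace_region_linear(a, c(2200, 3300))
  y <- a$intensity
  y[y < 0] <- 0  # replacement lines cannot reintroduce negatives, but be safe
  a <- with_intensity(a, y)
  a$id <- paste0(pair$device, "_water_vapor_reference")
  new_reference(a, "water_vapor", pair$device,
                c("ratio bg_a/bg_b", "to_absorbance", "interpolate dw=1",
                  "atmospheric_correct co2 2250-2450",
                  "normalize anchor 2000", "subtract 1", "clamp negatives",
                  "replace_region_linear 600-1200",
                  "replace_region_linear 2200-3300"))
}

#' Write a reference spectrum as CSV plus YAML provenance sidecar
#'
#' @param ref A `mir_reference`.
#' @param path Output CSV path; the sidecar is written next to it with
#'   extension `.yml`.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "mir_reference"))
  write_spectra(ref$spectrum, path)
  side <- sub("\\.csv$", ".yml", path)
  if (identical(side, path)) side <- paste0(path, ".yml")
  yaml::write_yaml(list(species = ref$species, device = ref$device,
                        id = ref$spectrum$id,
                        steps = as.list(ref$provenance)), side)
  invisible(path)
}

#' Read a reference spectrum written by [write_reference]
#'
#' @param path CSV path (sidecar `.yml` expected next to it).
#' @return A `mir_reference`.
#' @export
read_reference <- function(path) {
  side <- sub("\\.csv$", ".yml", path)
  if (identical(side, path)) side <- paste0(path, ".yml")
  if (!file.exists(side)) stop("provenance sidecar not found: ", side,
                               call. = FALSE)
  meta <- yaml::read_yaml(side)
  batch <- read_spectra(path, dialect = "wide", mode = "absorbance")
  new_reference(batch[[1L]], meta$species, meta$device,
                unlist(meta$steps))
}

#' Device-to-reference lookup
#'
#' Reads a YAML map `device: {water_vapor: <path>, co2: <path>}` plus an
#' optional `default` entry. Reference spectra for a device that has no
#' entry fall back to the default with a warning, mirroring the reuse of
#' references across devices when no background scans are available for a
#' device.
#'
#' @param path YAML lookup file.
#' @return A named list of class `reference_lookup`.
#' @export
read_reference_lookup <- function(path) {
  structure(yaml::read_yaml(path), class = "reference_lookup")
}

#' Resolve the reference spectra for a device
#'
#' @param lookup A `reference_lookup`.
#' @param device Device label.
#' @param base Directory that relative reference paths are resolved against.
#' @return A list with elements `water_vapor` and `co2`, each a
#'   `mir_reference`.
#' @export
refs_for_device <- function(lookup, device, base = ".") {
  entry <- lookup[[device]]
  if (is.null(entry)) {
    entry <- lookup[["default"]]
    if (is.null(entry)) {
      stop("no reference entry for device '", device,
           "' and no default entry", call. = FALSE)
    }
    warning("no reference entry for device '", device,
            "'; falling back to default", call. = FALSE)
  }
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  list(water_vapor = read_reference(resolve(entry$water_vapor)),
       co2 = read_reference(resolve(entry$co2)))
}
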