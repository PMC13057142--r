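# Lower convex hull (monotone chain) of the points (x, y); returns indices of
# hull vertices, always including the first and last point. Collinear interior
# points are dropped so the baseline is defined by true vertices only.
lower_hull_indices <- function(x, y) {
  n <- length(x)
  idx <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    while (k >= 2L) {
      a <- idx[k - 1L]; b <- idx[k]
      # cross product of (a->b) x (a->i): <= 0 means b is not a strict
      # right turn, i.e. above or on the chord, so it is not a lower vertex
      cr <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cr <= 0) k <- k - 1L else break
    }
    k <- k + 1L
    idx[k] <- i
  }
  idx[seq_len(k)]
}

#' Rubberband baseline correction
#'
#' The baseline is the piecewise-linear interpolation between the vertices of
#' the lower convex hull of the `(wavenumber, intensity)` point set; the
#' corrected spectrum is the input minus this baseline. The first and last
#' points are always hull vertices, so the corrected spectrum is zero at both
#' ends and nonnegative everywhere.
#'
#' @param s A [mir_spectrum] with at least 3 points and finite intensities.
#' @param return_baseline If `TRUE` return the baseline instead of the
#'   corrected spectrum.
#' @return A [mir_spectrum]: the corrected spectrum, or the baseline.
#' @export
rubberband <- function(s, return_baseline = FALSE) {
  stopifnot(is_mir_spectrum(s))
  if (length(s$wavenumber) < 3L) {
    stop("rubberband correction needs at least 3 points", call. = FALSE)
  }
  if (anyNA(s$intensity)) {
    stop("rubberband correction requires finite intensities", call. = FALSE)
  }
  hull <- lower_hull_indices(s$wavenumber, s$intensity)
  bl <- stats::approx(s$wavenumber[hull], s$intensity[hull],
                      xout = s$wavenumber, method = "linear", rule = 2)$y
  if (return_baseline) with_intensity(s, bl) else with_intensity(s, s$intensity - bl)
}

#' Rubberband correction returning spectrum, baseline and step log
#'
#' @param s A [mir_spectrum].
#' @return A list of class `mir_preprocess` with elements `spectrum`
#'   (corrected), `baseline`, and `steps`; `baseline + spectrum` reproduces
#'   the input on the shared grid.
#' @export
rubberband_result <- function(s) {
  bl <- rubberband(s, return_baseline = TRUE)
  structure(list(spectrum = with_intensity(s, s$intensity - bl$intensity),
                 baseline = bl, steps = "rubberband"),
            class = "mir_preprocess")
}

#' Replace a spectral region by a straight line
#'
#' Intensities strictly inside the interval are replaced by the straight line
#' joining the intensities at the boundary grid points (the first and last
#' grid points inside the closed interval, which keep their values). Used to
#' excise the CO2 doublet region before baseline correction.
#'
#' @param s A [mir_spectrum].
#' @param range Numeric `c(a, b)` in cm^-1, strictly inside the spectrum's
#'   range.
#' @return A [mir_spectrum] with the region linearised.
#' @export
replace_region_linear <- function(s, range) {
  stopifnot(is_mir_spectrum(s))
  if (range[1] <= min(s$wavenumber) || range[2] >= max(s$wavenumber)) {
    stop("replacement region must lie strictly inside the spectrum",
         call. = FALSE)
  }
  inside <- which(s$wavenumber >= range[1] & s$wavenumber <= range[2])
  if (length(inside) < 3L) return(s)
  i0 <- inside[1L]
  i1 <- inside[length(inside)]
  y <- s$intensity
  y[inside] <- stats::approx(s$wavenumber[c(i0, i1)], y[c(i0, i1)],
                             xout = s$wavenumber[inside])$y
  with_intensity(s, y)
}

#' Savitzky-Golay smoothing residual
#'
#' Subtracts the Savitzky-Golay smoothed copy from the spectrum. The smooth
#' estimates the local average intensity; the residual is interpreted as the
#' noise component.
#'
#' @param s A [mir_spectrum].
#' @param window Odd filter length in points (default 21).
#' @param order Polynomial order (default 3), `order < window`.
#' @return A [mir_spectrum] holding the residual.
#' @export
savgol_residual <- function(s, window = 21L, order = 3L) {
  stopifnot(is_mir_spectrum(s))
  window <- as.integer(window)
  order <- as.integer(order)
  if (window %% 2L != 1L || window <= order || order < 0L) {
    stop("window must be odd and greater than order", call. = FALSE)
  }
  if (window > length(s$wavenumber)) {
    stop("window longer than spectrum", call. = FALSE)
  }
  sm <- signal::sgolayfilt(s$intensity, p = order, n = window)
  with_intensity(s, s$intensity - sm)
}

#' Normalize a spectrum
#'
#' @param s A [mir_spectrum].
#' @param method `"area"`/`"sum"` divide all intensities by their sum;
#'   `"at_wavenumber"` divides by the intensity at `anchor` so the anchored
#'   value becomes 1.
#' @param anchor Anchor wavenumber (cm^-1) for `method = "at_wavenumber"`.
#' @return The normalized [mir_spectrum].
#' @export
normalize_spectrum <- function(s, method = c("area", "sum", "at_wavenumber"),
                               anchor = NULL) {
  stopifnot(is_mir_spectrum(s))
  method <- match.arg(method)
  denom <- if (method == "at_wavenumber") {
    if (is.null(anchor)) stop("anchor required for at_wavenumber", call. = FALSE)
    intensity_at(s, anchor)
  } else {
    sum(s$intensity)
  }
  if (!is.finite(denom) || denom == 0) {
    stop("degenerate spectrum: zero or non-finite normalizer", call. = FALSE)
  }
  with_intensity(s, s$intensity / denom)
}

#' Total baseline-corrected spectral area
#'
#' The normalizer for all relative quality indicators: the spectrum is
#' clipped to `cfg$area_range`, the CO2 doublet region `cfg$co2_interp_range`
#' is replaced by a straight line (negative CO2 peaks would otherwise corrupt
#' the baseline), a rubberband correction is applied, and the corrected
#' intensities are summed.
#'
#' @param s A [mir_spectrum] covering `cfg$area_range`.
#' @param cfg A [qc_config].
#' @return A nonnegative scalar area.
#' @export
total_area <- function(s, cfg = qc_config()) {
  stopifnot(is_mir_spectrum(s))
  if (!covers_range(s, cfg$area_range)) {
    stop(sprintf("spectrum [%g, %g] does not cover the area range [%g, %g]",
                 min(s$wavenumber), max(s$wavenumber),
                 cfg$area_range[1], cfg$area_range[2]), call. = FALSE)
  }
  x <- clip_spectrum(s, cfg$area_range)
  x <- replace_region_linear(x, cfg$co2_interp_range)
  x <- rubberband(x)
  sum(x$intensity)
}

#' Extract a signed artifact peak region
#'
#' Clips to `range` and baseline corrects the region, keeping the sign of the
#' artifact. The sign is decided by comparing the intensity at the grid point
#' nearest `peak_max` with the chord joining the region's endpoint
#' intensities: below the chord means a negative artifact (less gas during
#' the sample scan than during the background scan), in which case the region
#' is negated, rubberband corrected, and negated back. Ties count as
#' positive. Endpoint intensities of the result are zero and the result is
#' single-signed for pure-artifact regions.
#'
#' @param s A [mir_spectrum] covering `range`.
#' @param range Numeric `c(a, b)` in cm^-1.
#' @param peak_max Diagnostic peak position (cm^-1) inside `range`.
#' @return The extracted region as a [mir_spectrum].
#' @export
extract_peak <- function(s, range, peak_max) {
  stopifnot(is_mir_spectrum(s))
  if (peak_max < range[1] || peak_max > range[2]) {
    stop("peak_max must lie inside range", call. = FALSE)
  }
  r <- clip_spectrum(s, range)
  if (length(r$wavenumber) < 3L) {
    stop("peak region has fewer than 3 points", call. = FALSE)
  }
  n <- length(r$wavenumber)
  chord <- stats::approx(r$wavenumber[c(1L, n)], r$intensity[c(1L, n)],
                         xout = r$wavenumber)$y
  d <- abs(r$wavenumber - peak_max)
  i <- which(d == min(d))[1L]
  if (r$intensity[i] < chord[i]) {
    neg <- rubberband(with_intensity(r, -r$intensity))
    with_intensity(r, -neg$intensity)
  } else {
    rubberband(r)
  }
}
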