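#' Quality-control configuration
#'
#' Houses every wavenumber range, anchor and threshold used by the quality
#' indicators. Defaults are the values used to validate the spectra:
#' total-area range \[699, 3999\] cm^-1, CO2 interpolation range
#' \[2250, 2450\], baseline diagnostic clip \[1400, 3400\] evaluated at 1400
#' cm^-1 with threshold `t_bc = 9e-5`, water-vapor region \[3780, 3920\] with
#' diagnostic peak at 3853, CO2 region \[2250, 2450\] with peak at 2362,
#' noise region \[2700, 2750\], Savitzky-Golay window 21 points of order 3,
#' and the preprocessing clip range \[650, 3990\].
#'
#' @param ... Named overrides of any default field.
#' @return A list of class `qc_config`.
#' @export
#' @examples
#' cfg <- qc_config()
#' cfg$t_bc
qc_config <- function(...) {
  cfg <- list(
    area_range = c(699, 3999),
    co2_interp_range = c(2250, 2450),
    bc_clip_range = c(1400, 3400),
    bc_eval = 1400,
    t_bc = 9e-5,
    wv_range = c(3780, 3920),
    wv_peak_max = 3853,
    co2_range = c(2250, 2450),
    co2_peak_max = 2362,
    noise_range = c(2700, 2750),
    savgol_window = 21L,
    savgol_order = 3L,
    preprocess_clip = c(650, 3990)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown qc_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  for (f in c("area_range", "co2_interp_range", "bc_clip_range", "wv_range",
              "co2_range", "noise_range", "preprocess_clip")) {
    if (length(cfg[[f]]) != 2L || cfg[[f]][1] >= cfg[[f]][2]) {
      stop(f, " must be an interval c(a, b) with a < b", call. = FALSE)
    }
  }
  if (cfg$t_bc <= 0) stop("t_bc must be positive", call. = FALSE)
  if (cfg$wv_peak_max < cfg$wv_range[1] || cfg$wv_peak_max > cfg$wv_range[2]) {
    stop("wv_peak_max must lie inside wv_range", call. = FALSE)
  }
  if (cfg$co2_peak_max < cfg$co2_range[1] ||
      cfg$co2_peak_max > cfg$co2_range[2]) {
    stop("co2_peak_max must lie inside co2_range", call. = FALSE)
  }
  structure(cfg, class = "qc_config")
}

#' Read a quality-control configuration from YAML
#'
#' Fields absent from the file keep their defaults.
#'
#' @param path YAML file with `qc_config` field names.
#' @return A `qc_config`.
#' @export
read_qc_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(qc_config, vals)
}

#' Detect whether a spectrum was already baseline corrected
#'
#' Organic-matter spectra that have not been baseline corrected carry a large
#' baseline absorbance at the low-wavenumber end. The diagnostic computes the
#' rubberband baseline of the CO2-interpolated, area-range-clipped spectrum,
#' clips that baseline to `cfg$bc_clip_range` (\[1400, 3400\] cm^-1 for a
#' uniform reference range), divides it by the total area, and reads the
#' normalized baseline intensity at `cfg$bc_eval` (1400 cm^-1). Values at or
#' below the threshold `cfg$t_bc` indicate an already corrected spectrum.
#'
#' @param s A [mir_spectrum] covering `cfg$area_range`.
#' @param cfg A [qc_config].
#' @return A list with `i1400` (normalized baseline intensity) and
#'   `is_baseline_corrected` (`i1400 <= cfg$t_bc`).
#' @export
baseline_diagnostic <- function(s, cfg = qc_config()) {
  area <- total_area(s, cfg)
  if (area == 0) stop("degenerate spectrum: zero total area", call. = FALSE)
  x <- clip_spectrum(s, cfg$area_range)
  x <- replace_region_linear(x, cfg$co2_interp_range)
  bl <- rubberband(x, return_baseline = TRUE)
  bl <- clip_spectrum(bl, cfg$bc_clip_range)
  i1400 <- intensity_at(bl, cfg$bc_eval) / area
  list(i1400 = i1400, is_baseline_corrected = i1400 <= cfg$t_bc)
}

# Simple-regression OLS (slope with intercept) via the classical centered
# sums, with the textbook standard error. The closed form keeps the identity
# slope(x, x) == 1 float-exact, which anchors the reference calibration.
ols_slope <- function(y, x) {
  n <- length(x)
  xc <- x - mean(x)
  yc <- y - mean(y)
  sxx <- sum(xc * xc)
  if (sxx == 0) stop("reference region has zero variance", call. = FALSE)
  slope <- sum(xc * yc) / sxx
  res <- yc - slope * xc
  se <- sqrt(sum(res * res) / (n - 2L) / sxx)
  list(estimate = slope, se = se, n = n)
}

#' Relative artifact contribution of a gas to a spectrum
#'
#' Both the query spectrum and the reference spectrum are passed through the
#' same path: the artifact region is extracted with [extract_peak] and
#' divided by the respective spectrum's [total_area]. The query region is
#' then modelled on the reference region by ordinary least squares (with
#' intercept); the slope is the relative contribution and its classical
#' standard error quantifies the fit uncertainty. Supplying the reference as
#' the query therefore returns a slope of exactly 1 with zero standard
#' error.
#'
#' @param s Query [mir_spectrum] covering `range` and `cfg$area_range`.
#' @param ref A `mir_reference`.
#' @param range Artifact region interval (cm^-1).
#' @param peak_max Diagnostic peak position (cm^-1).
#' @param cfg A [qc_config].
#' @return A list with `estimate`, `se`, `n` (points in the regression) and
#'   `flag` (`NA_character_` when clean). Missing coverage yields `NA`
#'   estimates plus a flag instead of an error.
#' @export
artifact_contribution <- function(s, ref, range, peak_max,
                                  cfg = qc_config()) {
  stopifnot(is_mir_spectrum(s), inherits(ref, "mir_reference"))
  if (!covers_range(s, range) || !covers_range(s, cfg$area_range)) {
    return(list(estimate = NA_real_, se = NA_real_, n = 0L,
                flag = sprintf("missing coverage of [%g, %g] or area range",
                               range[1], range[2])))
  }
  q <- extract_peak(s, range, peak_max)
  q <- with_intensity(q, q$intensity / total_area(s, cfg))
  r <- extract_peak(ref$spectrum, range, peak_max)
  r <- with_intensity(r, r$intensity / total_area(ref$spectrum, cfg))
  rv <- if (identical(r$wavenumber, q$wavenumber)) r$intensity else {
    stats::approx(r$wavenumber, r$intensity, xout = q$wavenumber, rule = 2)$y
  }
  out <- ols_slope(q$intensity, rv)
  out$flag <- NA_character_
  out
}

#' Relative water-vapor contribution
#'
#' [artifact_contribution] over the water-vapor region (default
#' \[3780, 3920\] cm^-1, diagnostic peak 3853 cm^-1).
#'
#' @inheritParams artifact_contribution
#' @param ref_wv Water-vapor `mir_reference`.
#' @return As [artifact_contribution].
#' @export
water_vapor_contribution <- function(s, ref_wv, cfg = qc_config()) {
  artifact_contribution(s, ref_wv, cfg$wv_range, cfg$wv_peak_max, cfg)
}

#' Relative CO2 contribution
#'
#' [artifact_contribution] over the CO2 region (default \[2250, 2450\]
#' cm^-1, diagnostic peak 2362 cm^-1).
#'
#' @inheritParams artifact_contribution
#' @param ref_co2 CO2 `mir_reference`.
#' @return As [artifact_contribution].
#' @export
co2_contribution <- function(s, ref_co2, cfg = qc_config()) {
  artifact_contribution(s, ref_co2, cfg$co2_range, cfg$co2_peak_max, cfg)
}

#' Relative noise level of a spectrum
#'
#' The spectrum is clipped to `cfg$area_range`, the CO2 region is replaced
#' by a straight line, a rubberband correction is applied, and the
#' Savitzky-Golay smoothing residual (window `cfg$savgol_window`, order
#' `cfg$savgol_order`) isolates the noise component. The residual is divided
#' by the sum of the rubberband-corrected intensities, clipped to
#' `cfg$noise_range` (\[2700, 2750\] cm^-1, free of sharp organic-matter
#' peaks), and the variance of the remaining values is returned. The result
#' is invariant under uniform intensity scaling and under addition of an
#' affine baseline.
#'
#' @param s A [mir_spectrum] covering `cfg$area_range`.
#' @param cfg A [qc_config].
#' @return Nonnegative scalar `c_noise`.
#' @export
noise_level <- function(s, cfg = qc_config()) {
  stopifnot(is_mir_spectrum(s))
  if (!covers_range(s, cfg$area_range)) {
    stop("spectrum does not cover the area range", call. = FALSE)
  }
  x <- clip_spectrum(s, cfg$area_range)
  x <- replace_region_linear(x, cfg$co2_interp_range)
  x <- rubberband(x)
  denom <- sum(x$intensity)
  if (denom == 0) stop("degenerate spectrum: zero total area", call. = FALSE)
  res <- savgol_residual(x, window = cfg$savgol_window,
                         order = cfg$savgol_order)
  res <- with_intensity(res, res$intensity / denom)
  res <- clip_spectrum(res, cfg$noise_range)
  stats::var(res$intensity)
}

#' Quality-control report for a batch of spectra
#'
#' Computes every quality indicator per spectrum and assembles them into a
#' data frame using the metadata column names under which the indicators are
#' stored (`mir_water_vapor_contribution_relative`, ...). Per-spectrum
#' failures (e.g. insufficient spectral coverage) become `NA` cells with an
#' entry in the `flags` column rather than errors.
#'
#' @param batch A [mir_batch], already interpolated to a 1 cm^-1 grid.
#' @param refs List with elements `water_vapor` and `co2`, each a
#'   `mir_reference` (e.g. from [refs_for_device]).
#' @param cfg A [qc_config].
#' @param include_hi Also compute the humification index `hi_1630_1090` on
#'   the rubberband-corrected, sum-normalized spectrum.
#' @return A data frame with one row per spectrum and columns `id`,
#'   `is_baseline_corrected`, `mir_water_vapor_contribution_relative`,
#'   `mir_water_vapor_contribution_relative_sd`,
#'   `mir_co2_contribution_relative`, `mir_co2_contribution_relative_sd`,
#'   `noise_level_relative`, `i1400`, `total_area`, optionally
#'   `hi_1630_1090`, and `flags`.
#' @export
qc_report <- function(batch, refs, cfg = qc_config(), include_hi = FALSE) {
  stopifnot(inherits(batch, "mir_batch"))
  if (!length(batch)) {
    cols <- c("id", "is_baseline_corrected",
              "mir_water_vapor_contribution_relative",
              "mir_water_vapor_contribution_relative_sd",
              "mir_co2_contribution_relative",
              "mir_co2_contribution_relative_sd",
              "noise_level_relative", "i1400", "total_area",
              if (include_hi) "hi_1630_1090", "flags")
    out <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)),
                                         cols))
    return(out)
  }
  rows <- lapply(batch, function(s) {
    flags <- character(0)
    grab <- function(expr, what) {
      tryCatch(expr, error = function(e) {
        flags <<- c(flags, paste0(what, ": ", conditionMessage(e)))
        NULL
      })
    }
    area <- grab(total_area(s, cfg), "total_area")
    bd <- grab(baseline_diagnostic(s, cfg), "baseline_diagnostic")
    wv <- grab(water_vapor_contribution(s, refs$water_vapor, cfg),
               "water_vapor")
    co2 <- grab(co2_contribution(s, refs$co2, cfg), "co2")
    nz <- grab(noise_level(s, cfg), "noise")
    if (!is.null(wv) && !is.na(wv$flag)) flags <- c(flags, wv$flag)
    if (!is.null(co2) && !is.na(co2$flag)) flags <- c(flags, co2$flag)
    hi <- if (include_hi) {
      grab({
        p <- normalize_spectrum(rubberband(clip_spectrum(
          s, cfg$preprocess_clip)), method = "sum")
        humification_index(p)$value
      }, "hi_1630_1090")
    } else NULL
    row <- data.frame(
      id = s$id,
      is_baseline_corrected =
        if (is.null(bd)) NA else bd$is_baseline_corrected,
      mir_water_vapor_contribution_relative =
        if (is.null(wv)) NA_real_ else wv$estimate,
      mir_water_vapor_contribution_relative_sd =
        if (is.null(wv)) NA_real_ else wv$se,
      mir_co2_contribution_relative =
        if (is.null(co2)) NA_real_ else co2$estimate,
      mir_co2_contribution_relative_sd =
        if (is.null(co2)) NA_real_ else co2$se,
      noise_level_relative = if (is.null(nz)) NA_real_ else nz,
      i1400 = if (is.null(bd)) NA_real_ else bd$i1400,
      total_area = if (is.null(area)) NA_real_ else area,
      stringsAsFactors = FALSE
    )
    if (include_hi) row$hi_1630_1090 <- if (is.null(hi)) NA_real_ else hi
    row$flags <- paste(flags, collapse = "; ")
    row
  })
  do.call(rbind, rows)
}

#' Write a quality-control report CSV
#'
#' Numeric cells use 10 significant digits; missing indicators are written as
#' empty cells.
#'
#' @param report Data frame from [qc_report].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  out <- report
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), "",
                         formatC(out[[j]], format = "g", digits = 10))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}
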