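#' Construct a mid-infrared spectrum
#'
#' A `mir_spectrum` holds one spectrum: a strictly increasing wavenumber grid
#' (cm^-1), the corresponding intensities, the intensity mode, an identifier
#' and free-form metadata.
#'
#' @param wavenumber Numeric vector of wavenumbers in cm^-1, strictly
#'   increasing, length >= 2.
#' @param intensity Numeric vector of intensities, same length as
#'   `wavenumber`. Absorbance units (AU) for mode `"absorbance"`,
#'   transmission fraction for `"transmission"`, or a dimensionless ratio of
#'   two single-beam scans for `"ratio"`. `NA` marks explicitly missing
#'   values; non-finite values are rejected.
#' @param mode One of `"absorbance"`, `"transmission"`, `"ratio"`.
#' @param id Character identifier.
#' @param metadata Named list of additional metadata.
#'
#' @return An object of class `mir_spectrum`.
#' @export
#' @examples
#' s <- mir_spectrum(1000:1010, rep(0.5, 11), id = "a")
#' s
mir_spectrum <- function(wavenumber, intensity,
                         mode = c("absorbance", "transmission", "ratio"),
                         id = "spectrum", metadata = list()) {
  mode <- match.arg(mode)
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) < 2L) {
    stop("a spectrum needs at least 2 points", call. = FALSE)
  }
  if (length(wavenumber) != length(intensity)) {
    stop("wavenumber and intensity must have the same length", call. = FALSE)
  }
  if (anyNA(wavenumber) || any(!is.finite(wavenumber))) {
    stop("wavenumbers must be finite", call. = FALSE)
  }
  if (any(diff(wavenumber) <= 0)) {
    stop("wavenumbers must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(intensity) & !is.na(intensity))) {
    stop("intensities must be finite or NA", call. = FALSE)
  }
  structure(
    list(id = as.character(id)[1L], wavenumber = wavenumber,
         intensity = intensity, mode = mode, metadata = metadata),
    class = "mir_spectrum"
  )
}

#' @export
print.mir_spectrum <- function(x, ...) {
  cat(sprintf("<mir_spectrum> %s: %d points, %.6g-%.6g cm-1, mode %s\n",
              x$id, length(x$wavenumber), min(x$wavenumber),
              max(x$wavenumber), x$mode))
  invisible(x)
}

#' @export
length.mir_spectrum <- function(x) length(x$wavenumber)

#' @export
as.data.frame.mir_spectrum <- function(x, ...) {
  data.frame(wavenumber = x$wavenumber, intensity = x$intensity)
}

is_mir_spectrum <- function(x) inherits(x, "mir_spectrum")

spectrum_range <- function(s) range(s$wavenumber)

covers_range <- function(s, rng) {
  min(s$wavenumber) <= rng[1] && max(s$wavenumber) >= rng[2]
}

#' Construct a batch of spectra
#'
#' @param spectra List of [mir_spectrum] objects.
#' @return An object of class `mir_batch`; `shared_grid` attribute records
#'   whether all members sit on an identical wavenumber grid.
#' @export
mir_batch <- function(spectra) {
  if (!length(spectra) || !all(vapply(spectra, is_mir_spectrum, logical(1)))) {
    if (length(spectra)) {
      stop("all elements must be mir_spectrum objects", call. = FALSE)
    }
  }
  shared <- length(spectra) < 2L ||
    all(vapply(spectra[-1L], function(s) {
      identical(s$wavenumber, spectra[[1L]]$wavenumber)
    }, logical(1)))
  structure(spectra, shared_grid = shared, class = "mir_batch")
}

#' @export
print.mir_batch <- function(x, ...) {
  cat(sprintf("<mir_batch> %d spectra (shared grid: %s)\n", length(x),
              attr(x, "shared_grid")))
  invisible(x)
}

#' @export
`[.mir_batch` <- function(x, i) mir_batch(unclass(x)[i])

batch_ids <- function(batch) vapply(batch, function(s) s$id, character(1))

#' Read spectra from CSV
#'
#' Two dialects are supported. The wide dialect (canonical) has the
#' wavenumber in the first column and one column per spectrum; column names
#' become spectrum ids. The long dialect has columns `id`, `wavenumber`,
#' `intensity`.
#'
#' @param path Path to a CSV file (UTF-8, `"."` decimal mark, comma
#'   separated).
#' @param dialect `"wide"` or `"long"`.
#' @param mode Intensity mode assigned to all spectra read (the CSV itself
#'   carries no mode information).
#' @return A [mir_batch].
#' @export
read_spectra <- function(path, dialect = c("wide", "long"),
                         mode = "absorbance") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "wide") {
    if (ncol(d) < 1L) {
      stop("wide CSV needs a wavenumber column", call. = FALSE)
    }
    if (ncol(d) == 1L) return(mir_batch(list()))
    wn <- suppressWarnings(as.numeric(d[[1L]]))
    if (anyNA(wn)) {
      stop(sprintf("non-numeric wavenumber in column '%s' at row %d",
                   names(d)[1L], which(is.na(wn))[1L]), call. = FALSE)
    }
    spectra <- lapply(seq_len(ncol(d) - 1L) + 1L, function(j) {
      y <- d[[j]]
      bad <- !is.na(y) & is.na(suppressWarnings(as.numeric(y)))
      if (any(bad)) {
        stop(sprintf("non-numeric intensity in column '%s' at row %d",
                     names(d)[j], which(bad)[1L]), call. = FALSE)
      }
      mir_spectrum(wn, as.numeric(y), mode = mode, id = names(d)[j])
    })
  } else {
    need <- c("id", "wavenumber", "intensity")
    if (!all(need %in% names(d))) {
      stop("long CSV must have columns: ", paste(need, collapse = ", "),
           " (missing: ", paste(setdiff(need, names(d)), collapse = ", "), ")",
           call. = FALSE)
    }
    ids <- unique(d$id)
    spectra <- lapply(ids, function(i) {
      di <- d[d$id == i, , drop = FALSE]
      o <- order(di$wavenumber)
      mir_spectrum(di$wavenumber[o], as.numeric(di$intensity[o]),
                   mode = mode, id = i)
    })
  }
  mir_batch(spectra)
}

#' Write spectra to a wide CSV
#'
#' All spectra must share one wavenumber grid. Values are written with a
#' fixed number of significant digits (default 15, enough for 1e-12
#' round-trip fidelity) so repeated runs produce byte-identical files.
#'
#' @param batch A [mir_batch] (or single [mir_spectrum]).
#' @param path Output path; parent directories are created.
#' @param digits Significant digits used for formatting.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(batch, path, digits = 15) {
  if (is_mir_spectrum(batch)) batch <- mir_batch(list(batch))
  if (!attr(batch, "shared_grid")) {
    stop("wide CSV output requires a shared wavenumber grid", call. = FALSE)
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) formatC(x, format = "g", digits = digits)
  cols <- c(list(wavenumber = fmt(batch[[1L]]$wavenumber)),
            stats::setNames(lapply(batch, function(s) fmt(s$intensity)),
                            batch_ids(batch)))
  utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                   row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Interpolate a spectrum onto a regular wavenumber grid
#'
#' Linear interpolation onto the grid of multiples of `dw` between
#' `ceiling(min)` and `floor(max)` of the input range (consecutive integers
#' for `dw = 1`); no extrapolation. Missing values inside the spectrum are
#' bridged linearly; leading/trailing missing values are dropped.
#'
#' @param s A [mir_spectrum].
#' @param dw Grid spacing in cm^-1 (default 1).
#' @return A [mir_spectrum] on the regular grid.
#' @export
interpolate_to_grid <- function(s, dw = 1) {
  stopifnot(is_mir_spectrum(s))
  if (!is.numeric(dw) || length(dw) != 1L || dw <= 0) {
    stop("dw must be a positive number", call. = FALSE)
  }
  keep <- !is.na(s$intensity)
  if (sum(keep) < 2L) stop("not enough non-missing points", call. = FALSE)
  x <- s$wavenumber[keep]
  y <- s$intensity[keep]
  lo <- ceiling(min(x) / dw) * dw
  hi <- floor(max(x) / dw) * dw
  if (hi < lo) stop("input range too short for grid spacing dw", call. = FALSE)
  grid <- seq(lo, hi, by = dw)
  yi <- stats::approx(x, y, xout = grid, method = "linear", rule = 1)$y
  mir_spectrum(grid, yi, mode = s$mode, id = s$id, metadata = s$metadata)
}

#' Clip a spectrum to a wavenumber interval
#'
#' Retains exactly the grid points with `a <= wavenumber <= b` (closed
#' interval).
#'
#' @param s A [mir_spectrum].
#' @param range Numeric `c(a, b)` with `a < b`, in cm^-1.
#' @return The clipped [mir_spectrum].
#' @export
clip_spectrum <- function(s, range) {
  stopifnot(is_mir_spectrum(s))
  if (length(range) != 2L || range[1] >= range[2]) {
    stop("range must be c(a, b) with a < b", call. = FALSE)
  }
  keep <- s$wavenumber >= range[1] & s$wavenumber <= range[2]
  if (sum(keep) < 2L) {
    stop(sprintf("interval [%g, %g] contains fewer than 2 grid points",
                 range[1], range[2]), call. = FALSE)
  }
  mir_spectrum(s$wavenumber[keep], s$intensity[keep], mode = s$mode,
               id = s$id, metadata = s$metadata)
}

#' Convert transmission or ratio intensities to absorbance
#'
#' `A = -log10(T)` pointwise. Values below `clamp` are clamped to `clamp`
#' first, so ratio-derived spectra with near-zero throughput do not produce
#' infinities; with `clamp = NULL` nonpositive values are an error.
#'
#' @param s A [mir_spectrum] in transmission or ratio mode.
#' @param clamp Lower clamp applied before the logarithm (default `1e-8`),
#'   or `NULL` to disable clamping.
#' @return The spectrum in absorbance mode.
#' @export
to_absorbance <- function(s, clamp = 1e-8) {
  stopifnot(is_mir_spectrum(s))
  if (s$mode == "absorbance") {
    stop("spectrum is already in absorbance mode", call. = FALSE)
  }
  y <- s$intensity
  if (is.null(clamp)) {
    if (any(y <= 0, na.rm = TRUE)) {
      stop("nonpositive transmission values; enable clamping", call. = FALSE)
    }
  } else {
    y <- pmax(y, clamp)
  }
  mir_spectrum(s$wavenumber, -log10(y), mode = "absorbance", id = s$id,
               metadata = s$metadata)
}

#' Intensity at a wavenumber
#'
#' Returns the intensity at the grid point nearest to `nu`; ties are broken
#' toward the lower wavenumber.
#'
#' @param s A [mir_spectrum].
#' @param nu Wavenumber in cm^-1, within the spectrum's range.
#' @return A single intensity value.
#' @export
intensity_at <- function(s, nu) {
  stopifnot(is_mir_spectrum(s))
  if (nu < min(s$wavenumber) || nu > max(s$wavenumber)) {
    stop(sprintf("wavenumber %g outside spectrum range [%g, %g]", nu,
                 min(s$wavenumber), max(s$wavenumber)), call. = FALSE)
  }
  d <- abs(s$wavenumber - nu)
  s$intensity[which(d == min(d))[1L]]
}

# internal: replace intensities, keeping grid/mode/id
with_intensity <- function(s, y) {
  mir_spectrum(s$wavenumber, y, mode = s$mode, id = s$id,
               metadata = s$metadata)
}
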