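#' Humification index
#'
#' Ratio of the intensities at two diagnostic wavenumbers on a preprocessed
#' (baseline-corrected, normalized) spectrum. The default bands, 1630 cm^-1
#' (aromatic C=C / carboxylate stretch, enriched in decomposed material) over
#' 1090 cm^-1 (polysaccharide C-O stretch, depleted during decomposition),
#' give a proxy for the degree of organic-matter decomposition. Intensities
#' are read at the nearest grid point (ties toward the lower wavenumber),
#' with no local averaging.
#'
#' @param s A preprocessed [mir_spectrum] covering both wavenumbers.
#' @param x1 Numerator wavenumber (cm^-1), default 1630.
#' @param x2 Denominator wavenumber (cm^-1), default 1090.
#' @return A list of class `mir_index` with `name` (e.g. `"hi_1630_1090"`),
#'   `value`, `x1`, `x2`.
#' @export
#' @examples
#' s <- mir_spectrum(1000:2000, 0.05 + 0.05 * exp(-((1000:2000) - 1630)^2 / 2e3))
#' humification_index(s)$value
humification_index <- function(s, x1 = 1630, x2 = 1090) {
  stopifnot(is_mir_spectrum(s))
  i1 <- intensity_at(s, x1)
  i2 <- intensity_at(s, x2)
  if (i2 == 0) {
    stop(sprintf("intensity at %g cm^-1 is zero; index undefined", x2),
         call. = FALSE)
  }
  structure(list(name = sprintf("hi_%g_%g", x1, x2), value = i1 / i2,
                 x1 = x1, x2 = x2),
            class = "mir_index")
}

#' @export
print.mir_index <- function(x, ...) {
  cat(sprintf("<mir_index> %s = %.6g\n", x$name, x$value))
  invisible(x)
}
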