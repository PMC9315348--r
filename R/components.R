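#' NIR component band library
#'
#' Pure-component absorption band lists used to synthesize wood spectra.
#' The default library has two components. "carbohydrate" carries the
#' cellulose/glucomannan O-H and C-H combination bands near 1,474,
#' 1,509, 2,062, 2,080 and 2,342 nm; "lignin" carries the aromatic C-H
#' and carbonyl bands near 1,130, 1,670, 1,903 and 2,240 nm. Brown rot
#' consumes the carbohydrate fraction while modifying (and relatively
#' enriching) lignin, so decayed spectra shift from the first set of
#' bands to the second.
#'
#' @param components named list; each element a data.frame with columns
#'   `center` (nm), `fwhm` (nm, full width at half maximum) and
#'   `amplitude` (absorbance units). Defaults to the two-component
#'   wood library.
#' @return An object of class `component_library` (a validated named
#'   list of band tables).
#' @export
component_library <- function(components = NULL) {
  if (is.null(components)) {
    components <- list(
      carbohydrate = data.frame(
        center    = c(1474, 1509, 2062, 2080, 2342),
        fwhm      = c(70,   70,   90,   90,   80),
        amplitude = c(0.45, 0.50, 0.55, 0.60, 0.35)),
      lignin = data.frame(
        center    = c(1130, 1670, 1903, 2240),
        fwhm      = c(80,   70,   100,  90),
        amplitude = c(0.30, 0.55, 0.45, 0.50)))
  }
  if (is.null(names(components)) || any(!nzchar(names(components))))
    stop("components must be a named list")
  for (nm in names(components)) {
    b <- components[[nm]]
    if (nrow(b)) {
      stopifnot(all(c("center", "fwhm", "amplitude") %in% names(b)))
      if (any(b$amplitude <= 0)) stop("amplitudes must be > 0 (", nm, ")")
      if (any(b$fwhm <= 0)) stop("band widths must be > 0 (", nm, ")")
      if (any(b$center < 930 | b$center > 2550))
        stop("band centers must lie within [930, 2550] nm (", nm, ")")
    }
  }
  structure(components, class = "component_library")
}

#' Synthesize pure-component absorbance spectra
#'
#' Each component spectrum is a sum of Gaussian peaks (parameterized by
#' center, FWHM, amplitude) on a smooth positive baseline that rises
#' gently with wavelength, as NIR absorbance baselines of wood do.
#' Bands whose center falls outside the wavelength grid are skipped
#' with a warning.
#'
#' @param wavelengths strictly increasing wavelength grid (nm).
#' @param library a [component_library()].
#' @param baseline length-2 numeric `c(offset, slope_total)`: baseline
#'   is `offset + slope_total * (lambda - min) / range`. Both must keep
#'   the spectrum nonnegative.
#' @return matrix `components x bands`, rownames = component names.
#' @export
make_component_spectra <- function(wavelengths, library = component_library(),
                                   baseline = c(0.15, 0.10)) {
  wavelengths <- as.numeric(wavelengths)
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  rng <- range(wavelengths)
  base <- baseline[1] + baseline[2] * (wavelengths - rng[1]) / diff(rng)
  out <- matrix(0, nrow = length(library), ncol = length(wavelengths),
                dimnames = list(names(library), NULL))
  for (nm in names(library)) {
    spec <- base
    b <- library[[nm]]
    for (i in seq_len(nrow(b))) {
      if (b$center[i] < rng[1] || b$center[i] > rng[2]) {
        warning(sprintf("band at %.0f nm outside wavelength range [%.0f, %.0f]; skipped",
                        b$center[i], rng[1], rng[2]))
        next
      }
      ## Gaussian with the stated FWHM
      spec <- spec + b$amplitude[i] *
        exp(-4 * log(2) * ((wavelengths - b$center[i]) / b$fwhm[i])^2)
    }
    out[nm, ] <- spec
  }
  if (any(out < 0)) stop("negative absorbance in component spectra; check baseline")
  out
}
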