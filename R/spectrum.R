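#' Construct a wavelength-indexed spectrum
#'
#' The core spectral container used throughout the package: a strictly
#' increasing wavelength axis (nm) paired with dimensionless values
#' (absorbance in AU, relative emission intensity, or fractional
#' reflectance/transmittance).
#'
#' Reflectance and transmittance spectra are fractions and must lie in
#' `[0, 1 + tol]`; the small tolerance accommodates measurement slack around
#' unity (e.g. integrating-sphere calibration drift).
#'
#' @param wavelengths numeric vector, nm, strictly increasing, length >= 2.
#' @param values numeric vector of the same length, all finite.
#' @param kind one of `"absorbance"`, `"emission"`, `"reflectance"`,
#'   `"transmittance"`.
#' @param label free-text label carried along for printing.
#' @param tol upper slack allowed on fractional kinds (default 0.02).
#' @return An object of class `bbs_spectrum`: a list with elements
#'   `wavelengths`, `values`, `kind`, `label`.
#' @examples
#' s <- make_spectrum(400:700, dnorm(400:700, 550, 30), "emission")
#' print(s)
#' @export
make_spectrum <- function(wavelengths, values,
                          kind = c("absorbance", "emission",
                                   "reflectance", "transmittance"),
                          label = "", tol = 0.02) {
  kind <- match.arg(kind)
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  stop_if(length(wavelengths) < 2L, "spectrum needs at least 2 samples")
  stop_if(length(wavelengths) != length(values),
          "wavelengths and values must have equal length")
  stop_if(any(!is.finite(wavelengths)) || any(!is.finite(values)),
          "spectrum contains non-finite entries")
  stop_if(any(diff(wavelengths) <= 0),
          "wavelengths must be strictly increasing")
  if (kind %in% c("reflectance", "transmittance")) {
    stop_if(any(values < 0) || any(values > 1 + tol),
            sprintf("%s values must lie in [0, %g]", kind, 1 + tol))
  }
  structure(list(wavelengths = wavelengths, values = values,
                 kind = kind, label = label),
            class = "bbs_spectrum")
}

#' @export
print.bbs_spectrum <- function(x, ...) {
  cat(sprintf("<bbs_spectrum> %s%s: %d samples, %.6g-%.6g nm\n",
              x$kind, if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
as.data.frame.bbs_spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelengths, value = x$values)
}

# Restrict a spectrum to a wavelength window; errors if coverage is missing.
spectrum_window <- function(spectrum, window, min_samples = 3L,
                            what = "window") {
  stop_if(!inherits(spectrum, "bbs_spectrum"), "not a bbs_spectrum")
  stop_if(length(window) != 2L || window[1] >= window[2],
          "window must be an increasing (lo, hi) pair")
  idx <- which(spectrum$wavelengths >= window[1] &
                 spectrum$wavelengths <= window[2])
  stop_if(length(idx) == 0L, "window outside spectrum")
  stop_if(length(idx) < min_samples,
          sprintf("%s contains fewer than %d samples", what, min_samples))
  list(wl = spectrum$wavelengths[idx], val = spectrum$values[idx])
}

#' Locate a spectral peak within a window
#'
#' Finds the maximum of a spectrum inside a wavelength window and refines the
#' grid argmax by three-point parabolic interpolation, so peak positions are
#' robust to the sampling grid. A window in which all values are (numerically)
#' equal has no unique maximum: the window midpoint is returned with
#' `flat = TRUE`.
#'
#' @param spectrum a [make_spectrum()] object.
#' @param window length-2 numeric `(lo, hi)` in nm; must overlap the spectrum
#'   support and contain at least 3 samples.
#' @return list with `peak_wavelength` (nm), `peak_value`, and logical `flat`.
#' @examples
#' wl <- 600:720
#' s <- make_spectrum(wl, exp(-(wl - 673)^2 / (2 * 15^2)), "absorbance")
#' find_peak(s, c(600, 720))$peak_wavelength
#' @export
find_peak <- function(spectrum, window) {
  w <- spectrum_window(spectrum, window, 3L, "peak window")
  rng <- diff(range(w$val))
  if (rng <= .Machine$double.eps * max(1, max(abs(w$val)))) {
    return(list(peak_wavelength = mean(window), peak_value = w$val[1],
                flat = TRUE))
  }
  i <- which.max(w$val)
  ref <- parabolic_refine(w$wl, w$val, i)
  pk <- min(max(ref$x, window[1]), window[2])
  list(peak_wavelength = pk, peak_value = ref$y, flat = FALSE)
}

#' Red-edge position of a reflectance spectrum
#'
#' The red edge is the abrupt reflectance rise at the red/NIR boundary that
#' characterises chlorophyll-bearing leaves and, in chlorotic frogs, tissue
#' coloured by biliverdin-binding serpins. It is located as the wavelength of
#' the maximum first derivative of reflectance (central differences on the
#' native grid, optional Savitzky-Golay smoothing), refined parabolically.
#'
#' @param reflectance a reflectance-kind [make_spectrum()] object.
#' @param window length-2 nm window searched (default `c(650, 800)`).
#' @param smooth_window odd integer width for Savitzky-Golay smoothing of the
#'   reflectance before differencing; `0` (default) disables smoothing.
#' @return list with `wavelength` (nm) of the steepest rise, the `derivative`
#'   value there, and logical `flat` (constant slope, midpoint returned).
#' @export
red_edge_position <- function(reflectance, window = c(650, 800),
                              smooth_window = 0L) {
  stop_if(reflectance$kind != "reflectance",
          "red_edge_position expects a reflectance spectrum")
  w <- spectrum_window(reflectance, window, 5L, "red-edge window")
  val <- w$val
  if (smooth_window >= 3L) {
    stop_if(smooth_window %% 2L != 1L, "smooth_window must be odd")
    stop_if(smooth_window >= length(val),
            "smooth_window must be shorter than the windowed series")
    val <- as.numeric(signal::sgolayfilt(val, p = 2, n = smooth_window))
  }
  n <- length(val)
  # central differences on the native (possibly non-uniform) grid
  deriv <- numeric(n)
  deriv[1] <- (val[2] - val[1]) / (w$wl[2] - w$wl[1])
  deriv[n] <- (val[n] - val[n - 1]) / (w$wl[n] - w$wl[n - 1])
  deriv[2:(n - 1)] <- (val[3:n] - val[1:(n - 2)]) /
    (w$wl[3:n] - w$wl[1:(n - 2)])
  rng <- diff(range(deriv))
  if (rng <= 1e-12 * max(1, max(abs(deriv)))) {
    return(list(wavelength = mean(window), derivative = deriv[1], flat = TRUE))
  }
  i <- which.max(deriv)
  ref <- parabolic_refine(w$wl, deriv, i)
  list(wavelength = ref$x, derivative = ref$y, flat = FALSE)
}
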