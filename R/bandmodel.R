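#' Gaussian band mixture for chromophore spectra
#'
#' A `band_model` represents a chromophore absorption coefficient
#' epsilon(lambda) (M^-1 cm^-1) or a normalised emission profile as a sum of
#' Gaussian bands. Tetrapyrrole spectra (biliverdin free or serpin-bound) are
#' well captured by a violet Soret band, a red Q band and, for the
#' protein-bound pigment, a blue Q-band shoulder.
#'
#' @param centers numeric, band centres in nm.
#' @param sigmas numeric, band standard deviations in nm, all > 0.
#' @param amplitudes numeric, peak amplitudes (M^-1 cm^-1 for absorption,
#'   dimensionless for emission), all >= 0.
#' @param kind `"absorption"` or `"emission"`.
#' @return object of class `band_model`.
#' @examples
#' bv <- band_model(c(376, 672), c(18, 15), c(39900, 11200), "absorption")
#' eval_bands(bv, 376)
#' @export
band_model <- function(centers, sigmas, amplitudes,
                       kind = c("absorption", "emission")) {
  kind <- match.arg(kind)
  k <- length(centers)
  stop_if(k == 0L, "band_model needs at least one band")
  stop_if(length(sigmas) != k || length(amplitudes) != k,
          "centers, sigmas, amplitudes must have equal length")
  stop_if(any(sigmas <= 0), "band sigmas must be > 0")
  stop_if(any(amplitudes < 0), "band amplitudes must be >= 0")
  structure(list(centers = as.numeric(centers),
                 sigmas = as.numeric(sigmas),
                 amplitudes = as.numeric(amplitudes),
                 kind = kind),
            class = "band_model")
}

#' Evaluate a band model
#'
#' @param model a [band_model()].
#' @param wavelengths numeric vector, nm.
#' @return numeric vector of the Gaussian mixture evaluated at `wavelengths`;
#'   always >= 0.
#' @export
eval_bands <- function(model, wavelengths) {
  stop_if(!inherits(model, "band_model"), "not a band_model")
  out <- numeric(length(wavelengths))
  for (j in seq_along(model$centers)) {
    out <- out + model$amplitudes[j] *
      exp(-(wavelengths - model$centers[j])^2 / (2 * model$sigmas[j]^2))
  }
  out
}

#' @export
print.band_model <- function(x, ...) {
  cat(sprintf("<band_model> %s, %d band(s)\n", x$kind, length(x$centers)))
  for (j in seq_along(x$centers)) {
    cat(sprintf("  center %.6g nm  sigma %.6g nm  amplitude %.6g\n",
                x$centers[j], x$sigmas[j], x$amplitudes[j]))
  }
  invisible(x)
}

# Render a band model as a bbs_spectrum on a wavelength grid.
bands_to_spectrum <- function(model, wavelengths, label = "") {
  kind <- if (model$kind == "absorption") "absorbance" else "emission"
  make_spectrum(wavelengths, eval_bands(model, wavelengths), kind, label)
}
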