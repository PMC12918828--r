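# Beer-Lambert photometry: extinction coefficients, Q-band enhancement,
# relative quantum yield, denaturation metrics.

#' Fit a molar extinction coefficient from a dilution series
#'
#' Ordinary least squares of absorbance on concentration with a free
#' intercept (a baseline offset is tolerated but only the slope is
#' interpreted). The slope divided by the path length is the decadic molar
#' extinction coefficient epsilon at the stated wavelength.
#'
#' @param concentrations molar concentrations, >= 0, not all equal, length >= 3.
#' @param absorbances absorbance (AU), same length.
#' @param wavelength nm, recorded in the result.
#' @param path_cm optical path length in cm (default 1).
#' @return object of class `extinction_fit`: list with `epsilon`
#'   (M^-1 cm^-1), `intercept` (AU), `stderr_epsilon`, `r_squared`,
#'   `wavelength`, and logical `negative_slope` flag.
#' @examples
#' conc <- seq(0, 10e-6, length.out = 6)
#' fit_extinction(conc, 39900 * conc, 376)$epsilon
#' @export
fit_extinction <- function(concentrations, absorbances, wavelength,
                           path_cm = 1) {
  stop_if(length(concentrations) < 3L, "need at least 3 points")
  stop_if(length(concentrations) != length(absorbances),
          "concentrations and absorbances must have equal length")
  stop_if(any(concentrations < 0), "concentrations must be >= 0")
  stop_if(stats::sd(concentrations) == 0,
          "rank-deficient design: all concentrations equal")
  stop_if(path_cm <= 0, "path length must be positive")
  fit <- stats::lm(absorbances ~ concentrations)
  # a noiseless series triggers the harmless "essentially perfect fit" note
  sm <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2]) / path_cm
  se <- unname(sm$coefficients[2, 2]) / path_cm
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 1  # zero-variance response fits exactly
  structure(list(epsilon = slope,
                 intercept = unname(coef(fit)[1]),
                 stderr_epsilon = se,
                 r_squared = max(0, min(1, r2)),
                 wavelength = wavelength,
                 negative_slope = slope < 0),
            class = "extinction_fit")
}

#' @export
print.extinction_fit <- function(x, ...) {
  cat(sprintf(
    "<extinction_fit> epsilon = %.6g +/- %.3g M^-1 cm^-1 at %g nm (R2 = %.4f)\n",
    x$epsilon, x$stderr_epsilon, x$wavelength, x$r_squared))
  if (x$negative_slope) cat("  warning: negative slope\n")
  invisible(x)
}

#' Q-band enhancement on serpin binding
#'
#' Fold increase of the Q-band extinction coefficient of serpin-bound
#' biliverdin over free biliverdin (peak-to-peak ratio).
#'
#' @param epsilon_holo_q Q-band epsilon of the holo-protein, M^-1 cm^-1, > 0.
#' @param epsilon_free_q Q-band epsilon of free biliverdin, M^-1 cm^-1, > 0.
#' @return dimensionless fold enhancement.
#' @examples
#' q_band_enhancement(36449, 11200)  # TpBBS vs free biliverdin
#' @export
q_band_enhancement <- function(epsilon_holo_q, epsilon_free_q) {
  stop_if(!is_scalar_num(epsilon_holo_q) || epsilon_holo_q <= 0,
          "epsilon_holo_q must be a positive number")
  stop_if(!is_scalar_num(epsilon_free_q) || epsilon_free_q <= 0,
          "epsilon_free_q must be a positive number")
  epsilon_holo_q / epsilon_free_q
}

# zero-intercept least-squares slope: the standard gradient used in the
# relative quantum-yield method.
zero_intercept_slope <- function(x, y) sum(x * y) / sum(x * x)

#' Relative fluorescence quantum yield (gradient method)
#'
#' Estimates a sample's quantum yield against a reference fluorophore of
#' known yield by comparing the gradients of integrated emission versus
#' absorbance over matched dilution series:
#' `QY = QY_ref * (grad_sample / grad_ref) * (n_sample / n_ref)^2`.
#' Gradients are zero-intercept least-squares slopes, the standard choice for
#' the relative method, where zero absorber implies zero emission.
#'
#' @param sample_series,reference_series data frames (or lists) with columns
#'   `absorbance` and `integrated_emission`; >= 3 points each, absorbances > 0.
#' @param qy_reference known quantum yield of the reference (fraction).
#' @param n_sample,n_reference solvent refractive indices (default equal).
#' @param validity_range absorbance range within which the linear
#'   (inner-filter-free) approximation is trusted; points outside raise a
#'   warning flag but are retained.
#' @return object of class `quantum_yield_result`: `qy`, `gradient_sample`,
#'   `gradient_reference`, `qy_reference`, `refractive_ratio_sq`,
#'   `out_of_range` (logical flag).
#' @examples
#' a <- seq(0.01, 0.1, length.out = 5)
#' s <- data.frame(absorbance = a, integrated_emission = 100 * a)
#' relative_quantum_yield(s, s, qy_reference = 0.28)$qy
#' @export
relative_quantum_yield <- function(sample_series, reference_series,
                                   qy_reference,
                                   n_sample = 1.333, n_reference = 1.333,
                                   validity_range = c(0.005, 0.12)) {
  check_series <- function(s, name) {
    a <- s$absorbance; f <- s$integrated_emission
    stop_if(is.null(a) || is.null(f),
            paste(name, "needs absorbance and integrated_emission"))
    stop_if(length(a) < 3L, paste(name, "needs >= 3 points"))
    stop_if(any(a <= 0), paste(name, "absorbances must be > 0"))
    list(a = a, f = f)
  }
  s <- check_series(sample_series, "sample_series")
  r <- check_series(reference_series, "reference_series")
  stop_if(!is_scalar_num(qy_reference) || qy_reference <= 0 ||
            qy_reference > 1, "qy_reference must be a fraction in (0, 1]")
  out_of_range <- any(c(s$a, r$a) < validity_range[1] |
                        c(s$a, r$a) > validity_range[2])
  if (out_of_range)
    warning("absorbance outside validity range; inner-filter bias possible",
            call. = FALSE)
  gs <- zero_intercept_slope(s$a, s$f)
  gr <- zero_intercept_slope(r$a, r$f)
  stop_if(gs <= 0 || gr <= 0, "nonpositive emission gradient")
  ratio_sq <- (n_sample / n_reference)^2
  structure(list(qy = qy_reference * (gs / gr) * ratio_sq,
                 gradient_sample = gs,
                 gradient_reference = gr,
                 qy_reference = qy_reference,
                 refractive_ratio_sq = ratio_sq,
                 out_of_range = out_of_range),
            class = "quantum_yield_result")
}

#' @export
print.quantum_yield_result <- function(x, ...) {
  cat(sprintf("<quantum_yield_result> QY = %.4g%% (reference %.3g)\n",
              100 * x$qy, x$qy_reference))
  invisible(x)
}

#' Chemical-denaturation metrics of a biliverdin-serpin complex
#'
#' On denaturation (e.g. 6 M GdnHCl) biliverdin dissociates from the serpin:
#' the Q-band absorbance collapses and the Soret band shifts hypsochromically
#' toward the free-pigment position (390 -> 376 nm). This summarises both
#' effects from native and denatured absorbance spectra.
#'
#' @param native,denatured absorbance-kind [make_spectrum()] objects, each
#'   covering 350-750 nm.
#' @param q_window,soret_window nm search windows for the Q and Soret peaks.
#' @return list with `q_fold_decrease` (native Q peak / denatured Q peak) and
#'   `soret_shift` (native Soret peak - denatured Soret peak, nm; positive
#'   for a hypsochromic shift on denaturation).
#' @export
denaturation_metrics <- function(native, denatured,
                                 q_window = c(600, 720),
                                 soret_window = c(350, 430)) {
  for (s in list(native, denatured)) {
    stop_if(s$kind != "absorbance", "spectra must be absorbance kind")
    stop_if(min(s$wavelengths) > 350 || max(s$wavelengths) < 750,
            "spectra must cover 350-750 nm")
  }
  qn <- find_peak(native, q_window)
  qd <- find_peak(denatured, q_window)
  sn <- find_peak(native, soret_window)
  sd_ <- find_peak(denatured, soret_window)
  stop_if(qd$peak_value <= 0, "denatured Q-band peak is nonpositive")
  list(q_fold_decrease = qn$peak_value / qd$peak_value,
       soret_shift = sn$peak_wavelength - sd_$peak_wavelength)
}
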