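# Two-state thermal denaturation of the A390/A376 absorbance ratio.
#
# Unfolding releases biliverdin from the serpin, shifting the Soret band from
# 390 nm (bound) to 376 nm (free); the A390/A376 ratio therefore falls
# through the transition and its steepest descent marks the melting
# temperature.

R_GAS_KJ <- 8.314462618e-3  # kJ mol^-1 K^-1

#' Two-state van't Hoff unfolded fraction
#'
#' `f(T) = 1 / (1 + exp((dH_vH / R) * (1/T_K - 1/Tm_K)))` with temperatures
#' converted to Kelvin internally. At `T = Tm` the fraction is exactly 1/2;
#' `dh_vh` sets the sharpness of the transition.
#'
#' @param temperature degrees C (vectorised).
#' @param tm melting temperature, degrees C.
#' @param dh_vh van't Hoff enthalpy, kJ/mol, > 0.
#' @return fraction unfolded in `[0, 1]`.
#' @export
two_state_fraction <- function(temperature, tm, dh_vh) {
  stop_if(!is_scalar_num(dh_vh) || dh_vh <= 0, "dh_vh must be > 0")
  t_k <- temperature + 273.15
  tm_k <- tm + 273.15
  1 / (1 + exp((dh_vh / R_GAS_KJ) * (1 / t_k - 1 / tm_k)))
}

#' Melt-curve container
#'
#' @param temperatures degrees C, strictly increasing, length >= 10,
#'   spanning at least 10 C.
#' @param ratio A390/A376 absorbance ratio per temperature, > 0.
#' @return object of class `melt_curve`.
#' @export
melt_curve <- function(temperatures, ratio) {
  temperatures <- as.numeric(temperatures)
  ratio <- as.numeric(ratio)
  stop_if(length(temperatures) < 10L, "need at least 10 temperatures")
  stop_if(length(temperatures) != length(ratio),
          "temperatures and ratio must have equal length")
  stop_if(any(diff(temperatures) <= 0),
          "temperatures must be strictly increasing")
  stop_if(diff(range(temperatures)) < 10,
          "temperature span must be at least 10 C")
  stop_if(any(ratio <= 0) || any(!is.finite(ratio)),
          "ratio must be positive and finite")
  structure(list(temperatures = temperatures, ratio = ratio),
            class = "melt_curve")
}

#' Simulate a two-state A390/A376 melt curve
#'
#' `ratio(T) = ratio_native + (ratio_unfolded - ratio_native) * f(T)` plus
#' optional Gaussian noise, where `f` is [two_state_fraction()]. Native
#' baselines exceed the unfolded baseline because biliverdin release moves
#' Soret absorbance from 390 to 376 nm.
#'
#' @param tm melting temperature, degrees C.
#' @param dh_vh van't Hoff enthalpy, kJ/mol.
#' @param ratio_native,ratio_unfolded baselines, `ratio_native >
#'   ratio_unfolded > 0`.
#' @param grid strictly increasing temperatures, degrees C (default 20-90 C
#'   in 0.5 C steps).
#' @param noise_sd additive Gaussian noise SD on the ratio (default 0).
#' @param seed RNG seed for the noise; NULL uses the ambient RNG state.
#' @return a [melt_curve()].
#' @export
simulate_melt <- function(tm, dh_vh, ratio_native, ratio_unfolded,
                          grid = seq(20, 90, by = 0.5),
                          noise_sd = 0, seed = NULL) {
  stop_if(any(diff(grid) <= 0), "temperature grid must be strictly increasing")
  stop_if(!(ratio_native > ratio_unfolded && ratio_unfolded > 0),
          "require ratio_native > ratio_unfolded > 0")
  r <- ratio_native + (ratio_unfolded - ratio_native) *
    two_state_fraction(grid, tm, dh_vh)
  if (noise_sd > 0) {
    r <- r + with_local_seed(seed, rnorm(length(grid), 0, noise_sd))
  }
  melt_curve(grid, pmax(r, .Machine$double.eps))
}

#' Melting temperature from the derivative of a melt curve
#'
#' Smooths the ratio with a Savitzky-Golay (moving polynomial) filter, takes
#' central differences, and locates the extremum of `|dA/dT|`, refined by
#' parabolic interpolation. Working on the absolute derivative makes the
#' result independent of the baseline direction convention. If the smoothed
#' curve's total change is below `min_amplitude_frac` of its starting value
#' the protein is declared non-melting over the scanned range (the behaviour
#' of hyperstable relaxed-state serpins) and no Tm is reported.
#'
#' @param curve a [melt_curve()].
#' @param smooth_window odd Savitzky-Golay window length (default 7),
#'   shorter than the series.
#' @param min_amplitude_frac no-transition threshold as a fraction of the
#'   starting ratio (default 0.05).
#' @return object of class `melt_result`: `tm` (degrees C or NA),
#'   `transition_amplitude`, `derivative_curve` (data.frame temperature,
#'   dratio_dT), `status` (`"transition"` or `"no_transition"`).
#' @examples
#' mc <- simulate_melt(67, 400, 1.6, 0.8)
#' melting_temperature(mc)$tm
#' @export
melting_temperature <- function(curve, smooth_window = 7L,
                                min_amplitude_frac = 0.05) {
  stop_if(!inherits(curve, "melt_curve"), "not a melt_curve")
  n <- length(curve$ratio)
  stop_if(smooth_window %% 2L != 1L || smooth_window < 3L,
          "smooth_window must be an odd integer >= 3")
  stop_if(smooth_window >= n, "smooth_window must be shorter than the series")
  tt <- curve$temperatures
  sm <- as.numeric(signal::sgolayfilt(curve$ratio, p = 2, n = smooth_window))
  amplitude <- diff(range(sm))
  if (amplitude / sm[1] < min_amplitude_frac) {
    deriv <- c(diff(sm) / diff(tt), NA)
    return(structure(list(tm = NA_real_, transition_amplitude = amplitude,
                          derivative_curve = data.frame(
                            temperature = tt, dratio_dT = deriv),
                          status = "no_transition"),
                     class = "melt_result"))
  }
  deriv <- numeric(n)
  deriv[1] <- (sm[2] - sm[1]) / (tt[2] - tt[1])
  deriv[n] <- (sm[n] - sm[n - 1]) / (tt[n] - tt[n - 1])
  deriv[2:(n - 1)] <- (sm[3:n] - sm[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)])
  mag <- abs(deriv)
  i <- which.max(mag)
  ref <- parabolic_refine(tt, mag, i)
  structure(list(tm = ref$x, transition_amplitude = amplitude,
                 derivative_curve = data.frame(temperature = tt,
                                               dratio_dT = deriv),
                 status = "transition"),
            class = "melt_result")
}

#' @export
print.melt_result <- function(x, ...) {
  if (x$status == "no_transition") {
    cat("<melt_result> no transition detected over the scanned range\n")
  } else {
    cat(sprintf("<melt_result> Tm = %.2f C (amplitude %.3g)\n",
                x$tm, x$transition_amplitude))
  }
  invisible(x)
}
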