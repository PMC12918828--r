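# Seeded synthetic-data generators for every input the pipeline consumes.
# Defaults carry the measured photophysics of the three frog BBSs and free
# biliverdin, so noiseless generator output closes the loop with each
# analyser at the documented tolerance.

# Documented default band widths (nm). The widths are the dominant free
# choice in the synthesis: peak positions and amplitudes are measured, the
# widths are plausible values chosen once (see the methods vignette).
BAND_SIGMA <- c(soret = 18, q = 15, shoulder = 25, emission = 17)

bbs_catalog <- function() {
  list(
    TpBBS = list(
      soret = c(center = 390, eps = 52809),
      q = c(center = 673, eps = 36449),
      shoulder_frac = 0.35, shoulder_center = 620,
      emission_center = 697, qy = 0.0124),
    BpBBS = list(
      soret = c(center = 390, eps = 32072),
      q = c(center = 666, eps = 28034),
      shoulder_frac = 0.35, shoulder_center = 620,
      emission_center = 710, qy = 0.0139),
    SlBBS = list(
      soret = c(center = 390, eps = 38393),
      q = c(center = 666, eps = 26229),
      shoulder_frac = 0.35, shoulder_center = 620,
      emission_center = 707, qy = 0.0058),
    free_biliverdin = list(
      soret = c(center = 376, eps = 39900),
      q = c(center = 672, eps = 11200),
      shoulder_frac = 0, shoulder_center = 620,
      emission_center = 700, qy = 1e-4))
}

#' Synthetic BBS photophysics
#'
#' Builds Gaussian band models carrying the measured optical constants of
#' the recombinant biliverdin-binding serpins (and of free biliverdin):
#' Soret and Q-band peak extinction coefficients and positions, a blue
#' Q-band shoulder for the protein-bound pigment, the NIR emission peak, and
#' the intrinsic quantum yield. Band widths are documented defaults (Soret
#' sigma 18 nm, Q 15 nm, shoulder 25 nm, emission 17 nm).
#'
#' @param name one of `"TpBBS"`, `"BpBBS"`, `"SlBBS"`, `"free_biliverdin"`.
#' @param overrides named list overriding catalogue entries before the band
#'   models are built: any of `soret` (c(center, eps)), `q`,
#'   `shoulder_frac`, `shoulder_center`, `emission_center`, `qy`, `sigmas`
#'   (named like `BAND_SIGMA`).
#' @return object of class `bbs_photophysics`: list with `absorption` and
#'   `emission` [band_model()]s, `intrinsic_qy`, `name`.
#' @examples
#' tp <- make_bbs("TpBBS")
#' eval_bands(tp$absorption, 673)  # >= the Q-band peak coefficient
#' @export
make_bbs <- function(name = c("TpBBS", "BpBBS", "SlBBS", "free_biliverdin"),
                     overrides = list()) {
  name <- match.arg(name)
  spec <- bbs_catalog()[[name]]
  sig <- BAND_SIGMA
  if (!is.null(overrides$sigmas)) sig[names(overrides$sigmas)] <-
      overrides$sigmas
  for (f in setdiff(names(overrides), "sigmas")) spec[[f]] <- overrides[[f]]

  centers <- c(spec$soret[["center"]], spec$q[["center"]])
  sigmas <- c(sig[["soret"]], sig[["q"]])
  amps <- c(spec$soret[["eps"]], spec$q[["eps"]])
  if (spec$shoulder_frac > 0) {
    centers <- c(centers, spec$shoulder_center)
    sigmas <- c(sigmas, sig[["shoulder"]])
    amps <- c(amps, spec$shoulder_frac * spec$q[["eps"]])
  }
  absorption <- band_model(centers, sigmas, amps, "absorption")
  emission <- band_model(spec$emission_center, sig[["emission"]], 1,
                         "emission")
  stop_if(spec$qy <= 0 || spec$qy >= 1, "intrinsic_qy must lie in (0, 1)")
  structure(list(absorption = absorption, emission = emission,
                 intrinsic_qy = spec$qy, name = name),
            class = "bbs_photophysics")
}

#' @export
print.bbs_photophysics <- function(x, ...) {
  cat(sprintf("<bbs_photophysics> %s: emission %g nm, intrinsic QY %.3g%%\n",
              x$name, x$emission$centers[1], 100 * x$intrinsic_qy))
  invisible(x)
}

#' Synthetic fluorescence titration
#'
#' `F(c) = f0 + df * fraction_ligand_bound(c, L, Kd) * (1 + e)` with
#' multiplicative Gaussian noise `e ~ N(0, noise_sd_frac)` on the binding
#' signal. The default concentration ladder mirrors the plate layout of the
#' binding experiments (log-spaced 0.02-30 nM at 15 nM limiting biliverdin).
#'
#' @param kd true dissociation constant, molar.
#' @param ligand_total limiting ligand, molar (default 15e-9).
#' @param concentrations molar titrant ladder (default 12 log-spaced points
#'   0.02-30 nM).
#' @param f0 baseline fluorescence (default 50).
#' @param df binding-saturated fluorescence increment (default 1000).
#' @param noise_sd_frac multiplicative noise SD (default 0).
#' @param seed RNG seed; NULL uses the ambient RNG state.
#' @return a [titration_series()].
#' @export
make_titration <- function(kd, ligand_total = 15e-9,
                           concentrations = 10^seq(log10(0.02e-9),
                                                   log10(30e-9),
                                                   length.out = 12),
                           f0 = 50, df = 1000,
                           noise_sd_frac = 0, seed = NULL) {
  frac <- fraction_ligand_bound(concentrations, ligand_total, kd)
  eps <- if (noise_sd_frac > 0)
    with_local_seed(seed, rnorm(length(concentrations), 0, noise_sd_frac))
  else 0
  f <- f0 + df * frac * (1 + eps)
  titration_series(concentrations, ligand_total, f)
}

#' Synthetic melt curve
#'
#' Thin wrapper over [simulate_melt()] with the default thermal-scan grid
#' (20-90 C, 0.5 C sampling) and baselines typical of the A390/A376 ratio of
#' a biliverdin-serpin complex.
#'
#' @param tm melting temperature, degrees C.
#' @param dh_vh van't Hoff enthalpy, kJ/mol (default 400, a typical protein
#'   unfolding sharpness).
#' @param ratio_native,ratio_unfolded baselines (defaults 1.6, 0.8).
#' @param noise_sd additive noise SD (default 0).
#' @param seed RNG seed.
#' @inheritParams simulate_melt
#' @return a [melt_curve()].
#' @export
make_melt <- function(tm, dh_vh = 400, ratio_native = 1.6,
                      ratio_unfolded = 0.8, grid = seq(20, 90, by = 0.5),
                      noise_sd = 0, seed = NULL) {
  simulate_melt(tm, dh_vh, ratio_native, ratio_unfolded, grid,
                noise_sd, seed)
}

#' Synthetic Beer-Lambert dilution series
#'
#' `A = epsilon * c * path + intercept`, with optional multiplicative
#' Gaussian noise. A noiseless call returns the exact Beer-Lambert model.
#'
#' @param epsilon generating extinction coefficient, M^-1 cm^-1.
#' @param concentrations molar (default 6 points, 0-10 uM).
#' @param path_cm path length (default 1).
#' @param intercept baseline AU (default 0).
#' @param noise_sd_frac multiplicative noise SD (default 0).
#' @param seed RNG seed.
#' @return data.frame with `concentration` (M) and `absorbance` (AU).
#' @export
make_dilution_series <- function(epsilon,
                                 concentrations = seq(0, 10e-6,
                                                      length.out = 6),
                                 path_cm = 1, intercept = 0,
                                 noise_sd_frac = 0, seed = NULL) {
  a <- epsilon * concentrations * path_cm + intercept
  if (noise_sd_frac > 0) {
    a <- a * (1 + with_local_seed(
      seed, rnorm(length(concentrations), 0, noise_sd_frac)))
  }
  data.frame(concentration = concentrations, absorbance = a)
}

#' Synthetic slab reflectance/transmittance spectra
#'
#' Wraps [forward_rt()] over per-wavelength (mua, mus) pairs and adds seeded
#' multiplicative Gaussian noise; a noiseless call returns the exact forward
#' model.
#'
#' @param mua,mus mm^-1, vectors over wavelengths (recycled).
#' @param wavelengths nm tags.
#' @param slab a [slab_sample()].
#' @param noise_sd_frac multiplicative noise SD (default 0).
#' @param seed RNG seed.
#' @param quadrature_order forwarded to [forward_rt()].
#' @return list of [rt_measurement()] objects.
#' @export
make_slab_rt <- function(mua, mus, wavelengths, slab,
                         noise_sd_frac = 0, seed = NULL,
                         quadrature_order = 8L) {
  k <- length(wavelengths)
  mua <- rep_len(mua, k)
  mus <- rep_len(mus, k)
  noise <- if (noise_sd_frac > 0)
    with_local_seed(seed, rnorm(2 * k, 0, noise_sd_frac))
  else rep(0, 2 * k)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    rt <- forward_rt(mua[i], mus[i], slab, quadrature_order, wavelengths[i])
    out[[i]] <- rt_measurement(
      max(0, rt$reflectance * (1 + noise[2 * i - 1])),
      max(0, rt$transmittance * (1 + noise[2 * i])),
      wavelengths[i])
  }
  out
}
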