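# 2D layered-tissue Monte Carlo: fluorescence reabsorption in frog skin and
# BBS-laden lymph above a biological mirror, and the resulting
# concentration-dependent red shift of the escaping NIR emission.

#' Per-layer optical properties
#'
#' @param mua absorption coefficient, mm^-1, >= 0.
#' @param mus scattering coefficient, mm^-1, >= 0.
#' @param g scattering anisotropy, in (-1, 1) (default 0.9).
#' @param n refractive index, >= 1 (default 1.4).
#' @return object of class `optical_properties`.
#' @export
optical_properties <- function(mua, mus, g = 0.9, n = 1.4) {
  stop_if(mua < 0 || mus < 0, "mua and mus must be >= 0")
  stop_if(abs(g) >= 1, "g must lie in (-1, 1)")
  stop_if(n < 1, "refractive index must be >= 1")
  structure(list(mua = mua, mus = mus, g = g, n = n),
            class = "optical_properties")
}

#' Layered optical geometry for the 2D Monte Carlo
#'
#' Plane-parallel layers stacked top-down below an air half-space, over a
#' bottom boundary that is either an ideal specular reflector (the
#' broad-band biological mirror underlying frog lymph) or absorbing. The
#' default geometry follows the frog model: 0.1 mm skin over 0.1 mm lymph on
#' the mirror, discretised on a 300 x 300 grid of ~3.3 um pixels (1 mm^2
#' domain).
#'
#' @param layers list of layers, each a list with `name`, `thickness` (mm)
#'   and `properties` (an [optical_properties()]). All layers must share one
#'   refractive index (internal interfaces are index matched).
#' @param bottom_boundary `"ideal_specular_reflector"` or `"absorbing"`.
#' @param side_boundary `"absorbing"` (default) or `"reflecting"`; the
#'   reflecting option closes the cavity for lossless validation runs.
#' @param grid integer `(nx, ny)` pixels of the absorbed-weight map.
#' @param pixel_mm pixel width, mm.
#' @return object of class `layer_stack`.
#' @examples
#' st <- layer_stack(list(
#'   list(name = "skin", thickness = 0.1,
#'        properties = optical_properties(0, 10)),
#'   list(name = "lymph", thickness = 0.1,
#'        properties = optical_properties(0, 1))))
#' @export
layer_stack <- function(layers,
                        bottom_boundary = c("ideal_specular_reflector",
                                            "absorbing"),
                        side_boundary = c("absorbing", "reflecting"),
                        grid = c(300L, 300L), pixel_mm = 1 / 300) {
  bottom_boundary <- match.arg(bottom_boundary)
  side_boundary <- match.arg(side_boundary)
  stop_if(length(layers) < 1L, "need at least one layer")
  for (l in layers) {
    stop_if(is.null(l$thickness) || l$thickness <= 0,
            "each layer needs a positive thickness")
    stop_if(!inherits(l$properties, "optical_properties"),
            "each layer needs optical_properties")
  }
  ns <- vapply(layers, function(l) l$properties$n, numeric(1))
  stop_if(length(unique(ns)) > 1L,
          "all layers must share one refractive index")
  total <- sum(vapply(layers, function(l) l$thickness, numeric(1)))
  stop_if(total > grid[2] * pixel_mm + 1e-12,
          "layer thicknesses exceed the grid physical height")
  structure(list(layers = layers, bottom_boundary = bottom_boundary,
                 side_boundary = side_boundary,
                 grid = as.integer(grid), pixel_mm = pixel_mm,
                 width = grid[1] * pixel_mm, total_thickness = total),
            class = "layer_stack")
}

#' Fluorescence-simulation configuration
#'
#' Defaults mirror the frog emission model: wavelengths 650-820 nm at 1-nm
#' steps (171 points), an isotropic point source at the centre of the lymph
#' layer, a detector spanning the full top (air) boundary. The paper-scale
#' photon budget is 5e7 packets per wavelength; the desk default is 1e5.
#' The optional path gate `max_path_mm` emulates a finite integration time
#' (at n = 1.4, 5 ps corresponds to ~1.07 mm of path).
#'
#' @param wavelengths strictly increasing nm grid.
#' @param photons_per_wavelength packets per wavelength, >= 1e3.
#' @param seed integer master seed; per-wavelength substream seeds are
#'   derived deterministically, so results do not depend on loop order.
#' @param source_position `(x, y)` mm, or NULL for the lymph-layer centre.
#' @param detector `(x0, x1)` mm acceptance range on the top boundary, or
#'   NULL for the full width.
#' @param roulette_threshold,roulette_survival Russian-roulette parameters.
#' @param max_path_mm optional total path-length gate, mm.
#' @param source_mode `"isotropic"` or `"downward"` (collimated, for
#'   validation against Beer-Lambert).
#' @return object of class `fluor_sim_config`.
#' @export
fluor_sim_config <- function(wavelengths = seq(650, 820, by = 1),
                             photons_per_wavelength = 1e5,
                             seed = 1L,
                             source_position = NULL,
                             detector = NULL,
                             roulette_threshold = 1e-4,
                             roulette_survival = 0.1,
                             max_path_mm = NULL,
                             source_mode = c("isotropic", "downward")) {
  source_mode <- match.arg(source_mode)
  stop_if(any(diff(wavelengths) <= 0),
          "wavelengths must be strictly increasing")
  stop_if(photons_per_wavelength < 1e3,
          "photons_per_wavelength must be >= 1e3")
  structure(list(wavelengths = wavelengths,
                 photons_per_wavelength = as.integer(photons_per_wavelength),
                 seed = seed, source_position = source_position,
                 detector = detector,
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival,
                 max_path_mm = max_path_mm, source_mode = source_mode),
            class = "fluor_sim_config")
}

#' Absorption coefficient from chromophore concentration
#'
#' Converts a decadic molar extinction spectrum (M^-1 cm^-1) and a molar
#' concentration into the natural-log absorption coefficient in mm^-1 used
#' by the transport kernels: `mua = ln(10) * epsilon(lambda) * c / 10`.
#'
#' @param band_model an absorption-kind [band_model()].
#' @param concentration molar, >= 0.
#' @param wavelength nm (vectorised).
#' @return mua in mm^-1.
#' @examples
#' tp <- make_bbs("TpBBS")
#' mua_from_concentration(tp$absorption, 200e-6, 673)
#' @export
mua_from_concentration <- function(band_model, concentration, wavelength) {
  stop_if(concentration < 0, "concentration must be >= 0")
  stop_if(band_model$kind != "absorption",
          "band_model must be absorption kind")
  log(10) * eval_bands(band_model, wavelength) * concentration / 10
}

#' Sample a 2D Henyey-Greenstein scattering angle
#'
#' Inverse-CDF sample of the normalised 2D HG density
#' `p(theta) = (1 - g^2) / (2 pi (1 + g^2 - 2 g cos(theta)))` via
#' `theta = 2 atan(((1 - g) / (1 + g)) tan(pi (u - 1/2)))`. At `g = 0` this
#' reduces to a uniform angle on `(-pi, pi]`.
#'
#' @param g anisotropy, `|g| < 1`.
#' @param u uniform(0, 1) deviates (vectorised).
#' @return deflection angles in radians, in `(-pi, pi)`.
#' @export
sample_scatter_angle_2d <- function(g, u) {
  stop_if(abs(g) >= 1, "|g| must be < 1")
  stop_if(any(u <= 0) || any(u >= 1), "u must lie strictly in (0, 1)")
  2 * atan(((1 - g) / (1 + g)) * tan(pi * (u - 0.5)))
}

# Resolve source position and detector range against a stack.
resolve_source <- function(stack, config) {
  pos <- config$source_position
  if (is.null(pos)) {
    # centre of the last transport layer (the lymph layer in the default
    # two-layer frog stack)
    tops <- cumsum(c(0, vapply(stack$layers, function(l) l$thickness,
                               numeric(1))))
    k <- length(stack$layers)
    pos <- c(stack$width / 2, (tops[k] + tops[k + 1]) / 2)
  }
  det <- config$detector
  if (is.null(det)) det <- c(0, stack$width)
  list(pos = pos, det = det)
}

#' Propagate photon packets through a layer stack at one wavelength
#'
#' Weighted-packet 2D random walk: exponential steps in optical depth,
#' fractional absorption deposited into a pixel map, 2D Henyey-Greenstein
#' deflections, unpolarized Fresnel (with total internal reflection) at the
#' tissue/air interface, an ideal specular mirror or absorber below, and
#' Russian roulette with explicit weight bookkeeping so that
#' `detected + absorbed + lost = 1` to within 1e-6 by construction.
#'
#' @param stack a [layer_stack()] whose layer properties apply at this
#'   wavelength.
#' @param wavelength nm, used only to derive the per-wavelength RNG
#'   substream from `config$seed`.
#' @param config a [fluor_sim_config()].
#' @return list with `detected_weight`, `absorbed_map` (ny x nx matrix),
#'   `lost` (total), `lost_breakdown` (named vector), `conservation`
#'   (detected + absorbed + lost), `wavelength`.
#' @export
propagate <- function(stack, wavelength, config) {
  stop_if(!inherits(stack, "layer_stack"), "stack must be a layer_stack")
  stop_if(!inherits(config, "fluor_sim_config"),
          "config must be a fluor_sim_config")
  th <- vapply(stack$layers, function(l) l$thickness, numeric(1))
  y1 <- cumsum(th)
  y0 <- c(0, y1[-length(y1)])
  mua <- vapply(stack$layers, function(l) l$properties$mua, numeric(1))
  mus <- vapply(stack$layers, function(l) l$properties$mus, numeric(1))
  g <- stack$layers[[1]]$properties$g
  n_medium <- stack$layers[[1]]$properties$n
  src <- resolve_source(stack, config)
  stop_if(src$pos[2] <= 0 || src$pos[2] >= stack$total_thickness,
          "source must sit inside the layer stack")
  res <- cpp_propagate(
    y0, y1, mua, mus, g, n_medium, stack$width,
    as.integer(stack$bottom_boundary == "ideal_specular_reflector"),
    as.integer(stack$side_boundary == "reflecting"),
    stack$grid[1], stack$grid[2], stack$pixel_mm,
    src$pos[1], src$pos[2],
    as.integer(config$source_mode == "downward"),
    src$det[1], src$det[2],
    config$photons_per_wavelength,
    derive_seed(config$seed, wavelength),
    config$roulette_threshold, config$roulette_survival,
    if (is.null(config$max_path_mm)) -1 else config$max_path_mm)
  lost_breakdown <- c(side = res$lost_side,
                      bottom = res$lost_bottom,
                      outside_detector = res$lost_outside_detector,
                      roulette = res$lost_roulette,
                      path_gate = res$lost_maxpath)
  lost <- sum(lost_breakdown)
  list(detected_weight = res$detected,
       absorbed_map = res$absorbed,
       lost = lost,
       lost_breakdown = lost_breakdown,
       conservation = res$detected + sum(res$absorbed) + lost,
       wavelength = wavelength)
}

#' Simulated escaping fluorescence spectrum
#'
#' Runs [propagate()] once per wavelength of `config$wavelengths` with the
#' per-wavelength stack from `stack_builder`, and weights the detected
#' escape fraction by the intrinsic source emission spectrum. Reabsorption by
#' the chromophore's own Q band suppresses short-wavelength emission more
#' than long, red-shifting the escaping peak relative to the intrinsic one.
#'
#' @param stack_builder function `wavelength -> layer_stack`.
#' @param source_spectrum emission-kind [make_spectrum()] covering the
#'   wavelength grid (interpolated linearly onto it).
#' @param config a [fluor_sim_config()].
#' @return object of class `escape_spectrum`: `wavelengths`,
#'   `detected_weight`, `source_spectrum` (values on the grid), `escaping`
#'   (detected x source, peak-normalised), `conservation_max_error`.
#' @export
emission_spectrum <- function(stack_builder, source_spectrum, config) {
  stop_if(!is.function(stack_builder), "stack_builder must be a function")
  stop_if(source_spectrum$kind != "emission",
          "source_spectrum must be emission kind")
  wl <- config$wavelengths
  stop_if(min(wl) < min(source_spectrum$wavelengths) ||
            max(wl) > max(source_spectrum$wavelengths),
          "source_spectrum does not cover the wavelength grid")
  src <- approx(source_spectrum$wavelengths, source_spectrum$values, wl)$y
  detected <- numeric(length(wl))
  cons_err <- 0
  for (i in seq_along(wl)) {
    p <- propagate(stack_builder(wl[i]), wl[i], config)
    if (!is.finite(p$detected_weight))
      stop("propagate failed at wavelength ", wl[i], call. = FALSE)
    detected[i] <- p$detected_weight
    cons_err <- max(cons_err, abs(p$conservation - 1))
  }
  esc <- detected * src
  pk <- max(esc)
  stop_if(pk <= 0, "no escaping weight detected at any wavelength")
  structure(list(wavelengths = wl, detected_weight = detected,
                 source_spectrum = src, escaping = esc / pk,
                 conservation_max_error = cons_err),
            class = "escape_spectrum")
}

#' @export
print.escape_spectrum <- function(x, ...) {
  pk <- red_shift(x)
  cat(sprintf(
    "<escape_spectrum> %d wavelengths %.0f-%.0f nm; peak %.1f nm (intrinsic %.1f nm, shift %+.1f nm)\n",
    length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
    pk$peak_out, pk$peak_in, pk$shift))
  invisible(x)
}

#' Emission red shift of an escaping spectrum
#'
#' @param escape an [emission_spectrum()] result.
#' @return list with `peak_in` (intrinsic source peak, nm), `peak_out`
#'   (escaping-spectrum peak, nm) and `shift = peak_out - peak_in`.
#' @export
red_shift <- function(escape) {
  stop_if(!inherits(escape, "escape_spectrum"), "not an escape_spectrum")
  wl <- escape$wavelengths
  win <- range(wl)
  pin <- find_peak(make_spectrum(wl, escape$source_spectrum, "emission"), win)
  pout <- find_peak(make_spectrum(wl, escape$escaping, "emission"), win)
  list(peak_in = pin$peak_wavelength, peak_out = pout$peak_wavelength,
       shift = pout$peak_wavelength - pin$peak_wavelength)
}

#' Frog-tissue stack builder for a BBS chromophore
#'
#' Convenience constructor of the `wavelength -> layer_stack` function used
#' by [emission_spectrum()]: skin and lymph layers of the stated thicknesses
#' carry the chromophore at the given concentrations (absorption from its
#' band model), with wavelength-independent scattering, above the ideal
#' specular reflector.
#'
#' @param photophysics a [make_bbs()] object supplying the absorption band
#'   model.
#' @param concentration_skin,concentration_lymph molar BBS concentrations.
#' @param mus_skin,mus_lymph scattering coefficients, mm^-1 (defaults 10
#'   and 1).
#' @param g,n anisotropy and refractive index shared by both layers
#'   (defaults 0.9, 1.4).
#' @param thickness_skin,thickness_lymph mm (defaults 0.1 each).
#' @param side_boundary forwarded to [layer_stack()].
#' @return function mapping wavelength (nm) to a [layer_stack()].
#' @export
bbs_stack_builder <- function(photophysics,
                              concentration_skin = 0,
                              concentration_lymph = concentration_skin,
                              mus_skin = 10, mus_lymph = 1,
                              g = 0.9, n = 1.4,
                              thickness_skin = 0.1, thickness_lymph = 0.1,
                              side_boundary = "absorbing") {
  absorption <- photophysics$absorption
  function(wavelength) {
    layer_stack(list(
      list(name = "skin", thickness = thickness_skin,
           properties = optical_properties(
             mua_from_concentration(absorption, concentration_skin,
                                    wavelength),
             mus_skin, g, n)),
      list(name = "lymph", thickness = thickness_lymph,
           properties = optical_properties(
             mua_from_concentration(absorption, concentration_lymph,
                                    wavelength),
             mus_lymph, g, n))),
      bottom_boundary = "ideal_specular_reflector",
      side_boundary = side_boundary)
  }
}
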