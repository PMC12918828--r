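---
title: "Methods: BBS photophysics, binding and tissue-optics models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BBS photophysics, binding and tissue-optics models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbsoptics)
```

## The system

Several lineages of arboreal frogs are green not because of skin
chromatophores but because of chlorosis: high concentrations of the heme
catabolite biliverdin retained in blood, lymph and tissues by binding to a
serpin-family protein (a biliverdin-binding serpin, BBS). Binding red-shifts
the pigment's violet Soret band (~376 → ~390 nm), blue-shifts and intensifies
its red Q band (~672 → 666–675 nm, 2.5–3.5-fold), and rigidifies the
tetrapyrrole enough to produce near-infrared fluorescence (~697 nm emission,
extending past 700 nm into the tissue transparency window). `bbsoptics`
implements the quantitative analyses that characterise this system:
equilibrium binding titrations, thermal unfolding of the A390/A376 absorbance
ratio, spectrophotometric calibrations, a 2D Monte Carlo model of
fluorescence reabsorption in layered tissue, and adding–doubling slab optics
with inversion. A seeded synthetic-data module generates every input, so the
entire pipeline runs and is tested without external data.

## Binding model and regime diagnostics

The titration experiments hold the fluorogenic ligand (biliverdin) at a
fixed limiting concentration $L$ and titrate apo-protein $P$. The exact
1:1 mass-action bound fraction is

$$f = \frac{[PL]}{L},\qquad
[PL] = \frac{(P+L+K_d) - \sqrt{(P+L+K_d)^2 - 4PL}}{2},$$

computed internally in the rationalised form $2P/(S+\sqrt{S^2-4PL})$,
$S = P+L+K_d$, which is stable when $K_d \ll P, L$ (the subtraction in the
textbook branch cancels catastrophically there).

Two fitted models are exposed by `fit_apparent_kd()`:

* **`logistic4`** — the standard four-parameter logistic on
  $\log_{10}$ concentration with free Hill slope; its midpoint EC50 is the
  *apparent* $K_d$. When $L \gg K_d$ ("titration regime") this midpoint is a
  stoichiometric artefact pinned near $L/2$ regardless of affinity — at
  $L = 15$ nM the half-ligand artefact sits at 7.5 nM.
* **`exact_isotherm`** — $F = F_0 + \Delta F \cdot f(c; L, K_d)$, which
  reports the mass-action $K_d$ itself and remains identifiable in the
  binding regime ($L \lesssim K_d$).

`classify_regime()` labels an experiment *titration* when $L \ge 10\,K_d$,
*binding* when $L \le K_d$, and *intermediate* otherwise. The 10× and 1×
thresholds are conventions chosen so the half-ligand artefact is flagged;
both are configurable. Whether a published "sigmoidal-fit $K_d$" is an EC50
or an isotherm constant is often ambiguous, so the package reports both and
does not reconcile them.

Numerical choices: fits use Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) with 8 multistart seeds log-spaced in the midpoint
parameter, ties broken by residual norm then by the smaller $K_d$;
zero-concentration wells enter the log-axis fit at a pseudo-log floor one
decade below the smallest nonzero concentration. One structural caveat we
measured and accept: a free-Hill 4PL cannot represent the exact
piecewise-stoichiometric titration curve, so even noiseless EC50s carry a
+3–9% bias relative to $L/2$ depending on the plate design; recovery tests
therefore use the 5% tolerance rather than a tighter one.

`equilibration_time()` selects the scan from which all consecutive relative
changes stay below 2% (configurable); a series flat from the first scan
equilibrates at the first timepoint, and a series that never plateaus
returns the last timepoint with a flag.

## Thermal unfolding

Unfolding releases biliverdin, moving Soret absorbance from 390 nm
(serpin-bound) back to 376 nm (free), so the A390/A376 ratio falls through
the transition. Synthetic curves use the two-state van't Hoff form

$$f_u(T) = \frac{1}{1+\exp\!\big[(\Delta H_{vH}/R)(1/T - 1/T_m)\big]}$$

(temperatures in kelvin), with defaults $\Delta H_{vH} = 400$ kJ/mol (a
typical protein unfolding sharpness; no slope information is available for
these proteins), baselines 1.6 → 0.8, and a 20–90 °C grid sampled every
0.5 °C (the instrument ramps 1 °C/min; the acquisition cadence is a package
choice). `melting_temperature()` smooths with a Savitzky–Golay filter
(order 2, window 7 — whether the original analysis smoothed before
differentiating is unstated, so the window is explicit and configurable),
takes central differences, and reads $T_m$ at the parabolic-refined extremum
of $|d(\text{ratio})/dT|$; using the absolute derivative makes the result
independent of baseline direction. If the smoothed curve's total change is
below 5% of its starting value the result is `no_transition` — the behaviour
of the hyperstable relaxed-conformation glassfrog serpin, which shows no
ratio change up to 90 °C. The threshold is a package convention (the source
experiments declare flatness without a criterion) and is configurable.
Noiseless recovery is accurate to ~0.1 °C mid-range; the derivative peak of
a 0.5 °C grid quantises worst-case error to about half a grid step.

## Photometry

* `fit_extinction()` — ordinary least squares of absorbance on
  concentration with a free intercept (baseline offsets tolerated, slope
  reported), path length 1 cm by default. $\varepsilon$ in M⁻¹cm⁻¹.
* `q_band_enhancement()` — peak-to-peak ratio of holo-protein to
  free-pigment Q-band coefficients. Free biliverdin's Q coefficient is
  quoted at 672 nm while bound Q peaks sit at 666–675 nm; comparing
  peak-to-peak (rather than at a common wavelength) is the package default.
  With the measured coefficients this gives 2.50 (BpBBS), 2.34 (SlBBS) and
  3.25 (TpBBS) — the SlBBS value falls slightly below the commonly quoted
  2.5–3.5 band and is reported as computed rather than forced into it.
* `relative_quantum_yield()` — the gradient method:
  $QY = QY_{ref}\,(m_s/m_{ref})\,(n_s/n_{ref})^2$ with zero-intercept
  regression gradients of integrated emission on absorbance (standard
  relative-QY practice; zero absorber implies zero emission). Absorbances
  outside 0.005–0.12 trigger an inner-filter warning.
* `denaturation_metrics()` — Q-band fold decrease and Soret shift between
  native and denatured absorbance spectra; peak searches use Q 600–720 nm
  and Soret 350–430 nm windows, wide enough to bracket all reported peak
  positions, configurable.
* `red_edge_position()` — wavelength of maximum first derivative of
  reflectance (central differences, optional Savitzky–Golay smoothing),
  parabolically refined. Peak finding throughout uses three-point parabolic
  interpolation so results are robust to the sampling grid.

## 2D Monte Carlo fluorescence reabsorption

The in vivo emission spectrum of a chlorotic frog is red-shifted relative to
pure protein because emitted photons must escape through BBS-laden tissue
whose Q-band absorption eats the short-wavelength side of the emission band
(an inner-filter effect). The model is a weighted-packet Monte Carlo in a
genuinely two-dimensional geometry: directions live on the unit circle and
scattering uses the 2D Henyey–Greenstein density

$$p(\theta) = \frac{1-g^2}{2\pi\,(1+g^2-2g\cos\theta)},\qquad
\theta = 2\arctan\!\Big(\frac{1-g}{1+g}\tan\pi(u-\tfrac12)\Big),$$

whose inverse CDF is exact (`sample_scatter_angle_2d()`). The default stack
mirrors the frog geometry: 0.1 mm skin over 0.1 mm lymph on an ideal
specular reflector (the biological mirror under the lymph), air above, a
300 × 300 grid of ~3.3 µm pixels (1 mm² domain). Both layers carry the
chromophore; $\mu_a(\lambda) = \ln 10 \cdot \varepsilon(\lambda)\,c/10$
mm⁻¹ from the synthetic band models. Scattering coefficients are not
available for these tissues, so wavelength-independent defaults of 10 mm⁻¹
(skin) and 1 mm⁻¹ (lymph) are used with $g = 0.9$ and $n = 1.4$ everywhere;
all are configurable, and all layers must share one refractive index
(internal interfaces are index-matched; a mismatch raises an error rather
than being ignored).

Kernel mechanics: exponential steps in optical depth truncated at layer
boundaries; at each interaction a fraction $\mu_a/\mu_t$ of the packet
weight is deposited into the absorbed-weight map; the tissue/air interface
applies unpolarized Fresnel splitting with total internal reflection beyond
the critical angle, transmitting the escaping fraction deterministically
into the detector segment (a literal point detector would capture zero
weight in finite runs, so the "detector in the open-air layer" is an
acceptance segment on the top boundary, full-width by default and
configurable); the bottom mirror flips the vertical direction without loss;
side walls absorb by default. A `reflecting` side-wall option exists because
the lossless-cavity validation (no absorption, no scattering, mirror below)
only returns all weight to the detector when the cavity is closed —
near-horizontal rays otherwise leave through the sides. Russian roulette
(threshold 1e-4, survival 0.1) uses explicit ledger bookkeeping: survival
boosts are debited from the roulette loss bucket, so
`detected + absorbed + lost = 1` holds to better than 1e-6 *per run, by
construction*, not merely in expectation. An optional path-length gate
(`max_path_mm`; at $n = 1.4$, 5 ps ≈ 1.07 mm) emulates a finite integration
window; the default is CW. The kernel uses its own PCG32 generator:
per-wavelength substream seeds are derived deterministically from the master
seed, so results are independent of loop order and of R's RNG state.

`emission_spectrum()` runs one simulation per wavelength (default 650–820 nm
in 1-nm steps, i.e. 171 wavelengths; tests and the acceptance script use a
5-nm grid) and weights the detected escape fraction by the intrinsic
emission band; `red_shift()` compares intrinsic and escaping peaks. Desk
runs use 1e5 packets per wavelength; 5e7 reproduces the original
simulation's budget and is configuration only.

**What this model shows and does not show.** With zero chromophore the
escaping peak reproduces the intrinsic 697 nm emission; raising the
concentration red-shifts it monotonically (the package computes ~699, ~700,
~703, ~706, ~709 and ~713 nm at 0.1, 0.2, 0.5, 1, 2 and 5 mM under the
default conditions). The *magnitude* at any given concentration, however,
depends strongly on the synthetic Gaussian band widths — the dominant free
choice in the synthesis (σ: Soret 18, Q 15, shoulder 25, emission 17 nm,
chosen once to reproduce the printed peak positions and plausible band
shapes). Real BBS absorption and emission bands are broader and asymmetric,
and with the symmetric defaults the 500 µM escaping peak computed by the
acceptance script lands near 703 nm rather than at the ≥710 nm observed in
vivo. Direction, endpoint and monotonicity are the comparable quantities;
absolute escape fractions and the exact concentration-to-shift mapping are
not. An asymmetric two-Gaussian emission can be supplied through the band
model interface, but the defaults are deliberately left at the simple
symmetric choice rather than adjusted toward the in vivo number.

## Adding–doubling and inversion

`forward_rt()` computes total reflectance and transmittance of a
homogeneous slab under collimated normal incidence by discrete-ordinates
adding–doubling: radiance on a cosine quadrature with a node pinned at
$\mu = 1$ (Gauss–Radau, built by Golub's modified-Jacobi eigenvalue method)
so the collimated beam is a quadrature direction; azimuth-averaged
Henyey–Greenstein redistribution from its Legendre expansion
$\sum_k (2k+1) g^k P_k(\mu_i) P_k(\pm\mu_j)$, renormalised by a symmetric
diagonal scaling so scattered energy is conserved exactly on the quadrature;
single-scattering initialisation of a layer of optical thickness ≤ 1e-8
followed by repeated doubling (the initialisation error is first order in
the starting thickness — 1e-8 keeps conservation error below ~3e-7 at
optical depth 10). Operators are stored as
$\hat A = C^{1/2} A\, C^{1/2}$, $C = \mathrm{diag}(2\mu_i w_i)$, in which
composition is plain matrix algebra. For a bare (refractive) surface the
quadrature splits at the critical cosine and diagonal Fresnel interface
operators are added on both faces; integrating-sphere port geometry and
lost-light corrections are out of scope.

A caveat measured during validation: at $g = 0.9$ the forward peak is
under-resolved by low-order quadrature, biasing absolute totals (order 8
underestimates the reflectance of a $\mu_a{=}0.1, \mu_s{=}10$ mm⁻¹, 1 mm
slab by ~20%, order 16 by ~1.6%); totals converge by order 32, where they
agree with an independent plane-parallel Monte Carlo (the compiled
`cpp_mc_slab_1d` oracle, 3D HG sampling) within one Monte Carlo standard
error at 2e5 photons. Order 8 remains the default because the inverse
problem is self-consistent at any fixed order; use ~32 nodes when absolute
accuracy matters. The 2D tissue kernel is *not* used as this cross-check:
two-dimensional transport is quantitatively different physics from
plane-parallel 1D transport, which is why a dedicated 1D kernel exists.

`invert_rt()` recovers $(\mu_a, \mu_s)$ from a measured $(R, T)$ pair at
fixed $g$ and boundary: squared *relative* errors (so small transmittances
are not swamped by reflectance), a 12 × 12 log-spaced seeding grid, and
Nelder–Mead refinement on log-parameters; convergence requires relative
residual < 1e-3. $R + T \ge 1$ is rejected as non-physical. Inversion is
validated by round trips and grid-search oracles only — no published
recovered optical properties exist for these skins.

## Synthetic-data module

`make_bbs()` carries the measured photophysics of the three proteins and
free biliverdin (Soret/Q peak positions and coefficients, blue Q shoulder at
620 nm with 0.35 relative amplitude for bound pigment, emission centres
697/710/707 nm, intrinsic quantum yields 1.24%/1.39%/0.58%). Generators
(`make_titration`, `make_melt`, `make_dilution_series`, `make_slab_rt`) are
pure functions of (parameters, seed): noiseless calls return the exact
model, seeded calls are bit-reproducible and leave the ambient RNG state
untouched. Noise is Gaussian (multiplicative for plate fluorescence and
absorbance, additive for melt ratios); instrument artefacts beyond that
(drift, gain nonlinearity, stray light) are not emulated, so passing
recovery tests demonstrate estimator correctness under the stated noise
model, not robustness to real instrument pathology. The titration ladder
default (12 log-spaced points, 0.02–30 nM, $L = 15$ nM) mirrors the
reported plate design.

## Command-line interface

`bbs_cli()` (wrapped by `inst/cli/bbsoptics.R`) exposes the stages as
subcommands (`fit-kd`, `melt`, `extinction`, `qy`, `denat`, `mc-emission`,
`iad`, `rededge`, `synth`). Configuration is YAML plus `--key value` flag
overrides (flags win); every run writes a JSON result that echoes its fully
resolved configuration, and JSON outputs carry no wall-clock values, so
identical (config, seed) runs are byte-identical. Timing goes to the log
stream only.

## Problem sizes and reproducibility

The test suite and acceptance script size their simulations for a single
CPU: Monte Carlo validation runs use 1e4–1e5 packets per wavelength on a
5-nm grid, binding-recovery sweeps use 200 seeded replicates of 9-point
plates, and inversion oracles use forward grids of a few thousand
evaluations; the full suite completes in well under a minute apart from the
Monte Carlo blocks. All stochastic stages accept explicit seeds, and every
reported quantity is recomputed from scratch at run time.

## Known limitations

* Single 1:1 binding site; no cooperativity or kinetics.
* Two-state unfolding only; no ΔCp/ΔH extraction or reversibility checks.
* 2D (not 3D) photon transport; plane-parallel layers only; no polarization
  or time-resolved output; absolute escaping intensities are not comparable
  to measured spectra (see above).
* Adding–doubling assumes homogeneous slabs and normal collimated
  incidence; no sphere corrections; anisotropy is fixed during inversion.
* Synthetic Gaussian bands approximate real, asymmetric pigment spectra;
  band widths are the dominant free parameters.
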