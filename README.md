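# bbsoptics

Quantitative analyses for the photophysics of biliverdin-binding serpins
(BBSs) — the proteins that make many arboreal frogs leaf-green — and for the
tissue optics of the frogs that carry them.

Chlorotic ("green-blooded") treefrogs and glassfrogs retain high
concentrations of biliverdin, normally a short-lived heme breakdown product,
by binding it to a serpin with low-nanomolar affinity. Binding red-shifts the
pigment's Soret band (376 → ~390 nm), intensifies and structures its Q band
(2.5–3.5-fold at ~666–675 nm), and switches on near-infrared fluorescence
(~697 nm, detectable in vivo past 710 nm). This package implements the
analyses used to characterise such a system, for spectroscopists and
quantitative biologists working on protein–tetrapyrrole optics:

* **binding** — exact 1:1 isotherm
  `[PL] = ((P+L+Kd) − √((P+L+Kd)² − 4PL))/2`, four-parameter-logistic and
  exact-isotherm fits of fluorescence titrations, and titration-vs-binding
  regime diagnostics (when the limiting ligand L ≫ Kd, the fitted midpoint
  is the stoichiometric artefact ≈ L/2, not the affinity).
* **unfolding** — two-state van't Hoff melt curves of the A390/A376
  absorbance ratio; Tm from the parabolic-refined peak of |dA/dT|, with a
  no-transition verdict for hyperstable (relaxed-conformation) serpins.
* **spectra** — peak finding, extinction-coefficient fits (A = ε·c·l),
  relative quantum yield by the gradient method
  (QY = QY_ref · (m_s/m_ref) · (n_s/n_ref)²), Q-band enhancement,
  denaturation metrics, red-edge position of reflectance spectra.
* **tissue_mc** — a compiled 2D weighted-packet Monte Carlo
  (2D Henyey–Greenstein scattering, Fresnel/TIR air interface, ideal
  specular reflector) of fluorescence reabsorption in the skin/lymph stack,
  reproducing the concentration-dependent NIR emission red shift.
* **adding_doubling** — discrete-ordinates adding–doubling reflectance and
  transmittance of homogeneous slabs, plus inverse recovery of (µa, µs)
  from measured (R, T) at fixed g (IAD).
* **synth** — seeded generators for every input above, calibrated to the
  measured optical constants of TpBBS, BpBBS, SlBBS and free biliverdin, so
  the whole pipeline runs offline and deterministically.

## Worked example

```r
library(bbsoptics)

# A noiseless titration at 15 nM limiting biliverdin and true Kd = 0.1 nM:
# the sigmoidal fit reports the half-ligand artefact, not the affinity.
ts  <- make_titration(kd = 0.1e-9, ligand_total = 15e-9)
fit_apparent_kd(ts, "logistic4")
#> <binding_fit> model logistic4: apparent Kd = 7.844e-09 M (intermediate regime)
#>   hill 1.84, bottom 67.52, top 1162, residual norm 103

# Thermal melt generated at a 67 C midpoint, read back from the derivative.
melting_temperature(make_melt(67))
#> <melt_result> Tm = 66.93 C (amplitude 0.8)

# Q-band enhancement of TpBBS over free biliverdin from the measured
# extinction coefficients (M^-1 cm^-1).
q_band_enhancement(36449, 11200)
#> [1] 3.254375

make_bbs("TpBBS")
#> <bbs_photophysics> TpBBS: emission 697 nm, intrinsic QY 1.24%
```

The apparent Kd of 7.8 nM sits at ~L/2 (7.5 nM) because 15 nM ligand is far
above the true 0.1 nM Kd — the titration-regime artefact that
`classify_regime()` flags; the recovered Tm is within a tenth of a degree of
the generating midpoint, quantised by the 0.5 °C scan grid; and 3.25 is the
fold gain in red absorption that underlies the frogs' leaf-like colour
saturation.

A command-line wrapper over the same functions is installed at
`inst/cli/bbsoptics.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/bbsoptics.R", package="bbsoptics"))')" \
  synth --what titration --kd-nM 1 --out-dir out
```

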