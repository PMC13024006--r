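---
title: "Mixed-field radiobiology along spread-out Bragg peaks: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-field radiobiology along spread-out Bragg peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sobpbio)
```

## What this package computes

Ion-therapy beams (protons, helium, carbon) deposit dose in a water phantom
scored in 1 mm slices along the beam axis.  A clinical field is a
*spread-out Bragg peak* (SOBP): a weighted superposition of monoenergetic
("pristine") Bragg curves producing a flat high-dose plateau over the target
depth interval, here normalized to a 2 Gy plateau prescription.

In every slice the cells see a *mixed radiation field*: primaries of
different residual energies plus nuclear fragments.  Given a per-slice dose
decomposition by particle species and kinetic energy per nucleon, and a
radiosensitivity database of linear-quadratic (LQ) coefficients
$(\alpha_i, \beta_i)$ for monoenergetic beams, the package computes
dose-averaged coefficients per slice (Zaider–Rossi mixing):

$$\alpha = \frac{\sum_i \alpha_i D_i}{\sum_i D_i},\qquad
  \beta = \left(\frac{\sum_i \sqrt{\beta_i}\, D_i}{\sum_i D_i}\right)^2,$$

survival $S = \exp(-\alpha D - \beta D^2)$ at the slice's total dose $D$,
the RBE at equal survival (via the photon iso-effect dose
$D_x = 2E / (\alpha_x + \sqrt{\alpha_x^2 + 4\beta_x E})$ with
$E = \alpha D + \beta D^2$; this rationalized root avoids cancellation when
$\beta_x E \ll \alpha_x^2$), and the Gy-Eq dose $D_x = \mathrm{RBE}\cdot D$.
Two built-in cell lines anchor the photon response: squamous cell carcinoma
(SCC, $\alpha_x = 0.379$ Gy$^{-1}$, $\beta_x = 0.0299$ Gy$^{-2}$,
$\alpha/\beta = 12.68$ Gy) and human chordoma ($\alpha_x = 0.1567$
Gy$^{-1}$, $\beta_x = 0.0661$ Gy$^{-2}$, $\alpha/\beta = 2.37$ Gy).

Paired outputs of two transport engines are compared with RMSE and a 1D
gamma index (dose difference DD combined in quadrature with
distance-to-agreement DTA), with global normalization to the reference
maximum, a dose threshold, and pass-rate verdicts (good $\ge 95\%$,
acceptable $\ge 90\%$, in line with the TG-218 convention).  Because no
transport code is bundled, a synthetic generator emulates the paired
engines under controllable discrepancies.

## The analytic pristine kernel

Transport codes obtain pristine Bragg curves from full particle transport;
this package substitutes an analytic kernel whose only obligations are a
correct range, a realistically peaked shape, and a tunable fragment tail:

* range–energy: $R = (A/Z^2)\, a\, E^{p}$ cm with $E$ in MeV/u,
  $a = 0.0024$, $p = 1.755$.  The constants are calibrated so the clinical
  proton windows 46.2–58.2, 77.9–101.8 and 115.5–145.5 MeV map onto distal
  edges of 3, 8 and 15 cm; the helium and carbon windows then land within
  0.6 cm of their stated edges with no further tuning.
* stopping term: $\mathrm{d}D/\mathrm{d}z \propto (R - z)^{-(1 - 1/p)}$ for
  $z < R$, the depth profile implied by the same power law (integrable
  singularity at the range).
* range straggling: numerical convolution with a Gaussian of
  $\sigma_R = 0.012\,R^{0.935}$ cm, by midpoint quadrature on an internal
  grid of $\min(\sigma_R/4, 0.1\ \mathrm{mm})$.
* fragmentation tail (ions with $Z > 1$): an exponential beyond $R$ with
  amplitude `tail_fraction` (default 0.1) relative to the entrance dose and
  a 3 cm e-folding length.  Protons get no tail.
* normalization: unit entrance dose (first slice).

## SOBP weight design

Weights are fitted by non-negative least squares
(`pracma::lsqnonneg`) against a unit target on the plateau slices, then
rescaled so the composed plateau mean equals the prescription exactly.
Non-negativity is a hard physical constraint (beam weights are fluences).
Two choices matter for flatness:

* the deepest beam's range is extended one straggling width beyond the
  distal plateau edge, otherwise its smeared peak cannot hold the plateau
  through the final slice and the fit rings at the distal corner;
* `build_sobp()` uses one beam per millimetre of plateau span (minimum 12)
  so the plateau system is under-determined and the fit can null the
  inter-peak ripple.  With the default 1 mm slices this yields plateau
  ripple below 0.1% for all nine ion/depth scenarios; 12 beams suffice for
  a 1 cm plateau but leave percent-level ripple over 5 cm.

## The gamma index

For each evaluated reference point $(z_r, R_r)$,

$$\gamma(z_r) = \min_{z_e}\sqrt{\left(\frac{z_e - z_r}{\mathrm{DTA}}\right)^2
  + \left(\frac{E(z_e) - R_r}{\mathrm{DD}\cdot \max R}\right)^2},$$

where $E$ is the piecewise-linear interpolant of the evaluation profile and
the search window is $z_r \pm 4\,\mathrm{DTA}$ (clipped to the grid, with
flat extension beyond the ends).  On each linear segment of $E$ the
objective is a quadratic in $z_e$, so `gamma_1d()` minimises it *exactly*
per segment instead of discretizing the search position; a fixed-step
search cannot honestly certify per-point agreement at the $10^{-3}$ level
on profiles with gradients of order the normalization per DTA.
`gamma_1d_bruteforce()` is the deliberately independent cross-check: an
exhaustive scan at step DTA/100 over $z_r \pm 10\,\mathrm{DTA}$ with a
golden-section polish of the winning bracket.  The two agree to better than
$10^{-3}$ per point on randomized smooth profile pairs, which bounds the
residual discretization error of the oracle itself.

Defaults mirror clinical practice: dose comparisons use 3%/2 mm with a 10%
dose threshold; survival comparisons use the stricter 2%/2 mm and no
threshold, because a surviving fraction near 1 in the entrance channel is
as informative as one in the target (the threshold is a *dose* concept).
The threshold is applied to the reference profile only.  RMSE for physical
dose is computed on profiles divided by the reference plateau mean, making
it dimensionless and comparable across prescriptions; survival RMSE uses
raw surviving fractions.

## Multi-run statistics

Each simulated configuration consists of $n = 5$ independent runs
(nominally $2\times 10^6$ primaries each).  Per slice, the package reports
the mean over runs and the standard error of the mean
$\sigma_x = \sqrt{\sum_i (x_i - \bar x)^2 / (n(n-1))}$ for dose, alpha and
beta, and propagates them into survival to first order:

$$\sigma_S = S\sqrt{D^2\sigma_\alpha^2 + D^4\sigma_\beta^2 +
  (\alpha + 2\beta D)^2 \sigma_D^2}.$$

Covariances between the $\alpha$, $\beta$ and $D$ estimates are neglected
(the formula has no cross terms); a Monte Carlo sampling check in the test
suite confirms the delta-method value within 5% at 2% relative input
uncertainties.  Note that the per-slice mixing is scale-invariant, so
slice-level dose noise produces *zero* run-to-run spread in alpha and beta;
non-zero $\sigma_\alpha$ requires spectral (per-component) variation
between runs.

## The synthetic two-code generator

`generate_code_pair()` stands in for a pair of transport engines:

* code A decomposes the SOBP exactly: per beam and slice, a primary record
  with the local energy from the inverse range-energy relation; dose beyond
  each beam's range (straggling plus tail) is booked as species `"other"`
  for $Z > 1$ ions and as low-energy primaries for protons.  Per-slice
  record sums reproduce the composed profile to machine precision.
* code B regenerates every kernel at a range longer by `range_shift_mm`
  (the shift is analytic, not a resampling of the 1 mm-sampled curve, which
  would blur the distal edge) and multiplies the beyond-range dose by
  `tail_scale`.
* both codes receive `n_runs` independent per-slice relative Gaussian noise
  realizations (multiplicative, one factor per slice per run, matching the
  aggregate level at which the run statistics operate — not a per-primary
  Poisson model).

Default study conditions are a 0.5 mm range shift, tail scale 1.1, 1%
noise and 5 runs: the regime of two well-configured engines differing only
in nuclear models and sub-mm range calibration.  All stochastic operations
take explicit integer seeds and restore the global RNG state.

The synthetic radiosensitivity tables use a parametric LET response:
$\mathrm{LET} = k Z^2 / E^{0.8}$ keV/µm (scaled so a 10 MeV/u proton has
4.5 keV/µm) with
$\alpha(E) = \alpha_x (1 + g L/L_0)\,e^{-L/L_0}$ and
$\sqrt{\beta}(E) = \sqrt{\beta_x}\, e^{-L/(2L_0)}$, $L_0 = 80$ keV/µm,
$g = 3$.  This reproduces the *structure* of simulated survival databases
— photon limit at low LET, a rise to a single maximum, overkill decline,
$Z^2$ ordering at fixed energy per nucleon — but makes no claim of
numerical fidelity to any particular biophysical model.  Consequently the
end-to-end tests certify the pipeline (mixing, statistics, comparison
metrics), not the radiobiology of a real cell line.  Real-data features the
generator does not emulate: correlated noise between slices, per-fragment
energy spectra (fragments are lumped into the photon-fallback species),
angular/lateral effects, and energy-loss straggling of the spectra
themselves.

## Interpolation and degenerate-input conventions

* Radiosensitivity lookups interpolate $\alpha$ and $\sqrt{\beta}$
  linearly in $\log E$; $\sqrt{\beta}$ (not $\beta$) so that interpolation
  and mixing commute for flat tables.  Energies outside the tabulated grid
  clamp to the nearest endpoint with a warning.
* Species without database entries (including `"other"`) fall back to the
  photon coefficients, keeping the mixing denominator equal to the total
  physical dose.
* Slices with zero total dose have undefined mixed coefficients: survival
  is reported as 1, RBE as `NA`, Gy-Eq as 0, and such slices are excluded
  from comparisons via the dose threshold.
* Single-component mixing returns the component coefficients bitwise (no
  sqrt/square round trip).
* The quoted LQ sensitivity relation between relative dose and survival
  differences, $\Delta S/S = (\alpha D + \beta D^2)\,\Delta D/D$, is the
  commonly printed first-order factor; the exact logarithmic derivative of
  $S(D)$ gives $(\alpha D + 2\beta D^2)\,\Delta D/D$.  Both variants are
  exposed in `sensitivity_factor()` rather than silently correcting either;
  they coincide when $\beta = 0$.

## Problem sizes

The test suite and the acceptance script run the full pipeline at the study
scale: grids of 45–180 one-millimetre slices, 12–51 beams per SOBP, 5 runs
per engine, 9 ion/depth scenarios and 2 cell lines (18 comparisons), and
oracle-equivalence sweeps of 100 randomized profile pairs.  The complete
suite runs in well under a minute on one CPU; nothing is down-scaled from
the conditions described above.

## Known limitations

* 1D depth only; the 3 cm source/scoring radius is metadata and no lateral
  beam model is provided.
* The analytic kernel has no build-up, no nuclear attenuation of the
  primary fluence, and a single-exponential tail; it is adequate for
  property-level validation, not for absolute dosimetry.
* Only global-maximum gamma normalization is implemented (no local gamma,
  no 2D/3D).
* The database is indexed by kinetic energy per nucleon, not LET; LET
  appears only inside the synthetic generator.
* No covariance terms in the uncertainty propagation, and no
  bootstrap/jackknife alternatives to the run-based standard error.
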