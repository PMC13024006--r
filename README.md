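# sobpbio

Computational radiobiology of ion-therapy beams in R: spread-out Bragg
peak (SOBP) construction, mixed-field linear-quadratic cell survival, RBE
and Gy-Eq depth profiles, multi-run uncertainty propagation, and
quantitative comparison of paired depth profiles from two particle
transport engines with RMSE and 1D gamma-index analysis.

## Who it is for

Medical physicists and modellers who interface radiobiological models with
Monte Carlo transport codes and need to answer, reproducibly: *do two
transport engines (or two versions, physics lists, or implementations of a
biophysical interface) agree on the physical dose — and on the predicted
cell survival — along an SOBP, to clinical tolerances?*  Because transport
codes themselves are out of scope, the package includes a synthetic
generator that emulates two near-identical engines with controllable range
shift, fragmentation-tail amplitude differences and per-run statistical
noise, so the whole statistical pipeline can be exercised and validated
end to end.

## The models at the core

* **Mixed-field LQ coefficients** (Zaider–Rossi dose averaging), per
  1 mm depth slice:
  α = Σᵢ αᵢDᵢ / ΣᵢDᵢ, β = (Σᵢ √βᵢ Dᵢ / ΣᵢDᵢ)², where Dᵢ is the dose from
  radiation component *i* (a species at an energy) and (αᵢ, βᵢ) come from a
  per-species, energy-indexed radiosensitivity table.
* **Survival, RBE, Gy-Eq**: S = exp(−αD − βD²) at the slice total dose;
  the photon iso-effect dose Dₓ solves αₓDₓ + βₓDₓ² = αD + βD², giving
  RBE = Dₓ/D and Gy-Eq = Dₓ.  Built-in cell lines: SCC
  (αₓ = 0.379 Gy⁻¹, βₓ = 0.0299 Gy⁻², α/β = 12.68 Gy) and chordoma
  (αₓ = 0.1567 Gy⁻¹, βₓ = 0.0661 Gy⁻², α/β = 2.37 Gy).
* **SOBP design**: analytic pristine Bragg kernels (power-law stopping
  term convolved with Gaussian range straggling, optional exponential
  fragmentation tail), non-negative least-squares weights for a flat
  plateau, normalized to a 2 Gy prescription; opposing-field composition.
* **Run statistics**: per-slice mean and standard error of the mean over
  n ≥ 2 independent runs; first-order propagation
  σ_S = S·√(D²σ_α² + D⁴σ_β² + (α + 2βD)²σ_D²).
* **Comparison**: RMSE = √(Σ(y_A − y_B)²/N) and a 1D gamma index with
  DD/DTA criteria (defaults 3%/2 mm with 10% threshold for dose, 2%/2 mm
  for survival), global normalization to the reference maximum, pass-rate
  verdicts (good ≥ 95%, acceptable ≥ 90%).  `gamma_1d()` minimises the
  gamma objective exactly per linear segment of the evaluation curve;
  `gamma_1d_bruteforce()` is an independent dense-grid oracle.

## Worked example

Design a carbon SOBP over 5–8 cm from the 1730–2290 MeV energy window,
emulate two transport codes (0.5 mm range shift, 10% fragment-tail
difference, 1% per-slice noise, 5 runs each), and compare dose and
survival:

```r
library(sobpbio)

sob <- build_sobp("C", c(50, 80), e_min = 1730/12, e_max = 2290/12)
tabs <- list(
  SCC      = synth_alpha_beta_table(synth_radbio_params(cell_line_scc())),
  chordoma = synth_alpha_beta_table(synth_radbio_params(cell_line_chordoma())))

pair <- generate_code_pair(sob$plan, sob$kernels,
          perturbation_params(range_shift_mm = 0.5, tail_scale = 1.1,
                              noise_rel = 0.01, n_runs = 5, seed = 42))
cmp <- compare_code_pair(pair, c(50, 80), tabs)
cmp$dose
#> comparison_report [dose]: RMSE 0.03551, pass 100.0%, mean gamma 0.137 -> good
cmp$survival$SCC
#> comparison_report [SCC]: RMSE 0.01904, pass 100.0%, mean gamma 0.111 -> good
cmp$survival$chordoma
#> comparison_report [chordoma]: RMSE 0.01267, pass 100.0%, mean gamma 0.124 -> good
```

The dose report says: after normalizing both mean dose profiles to the
reference plateau mean, the root-mean-square discrepancy is 0.036 (3.6% of
the plateau), every reference slice above the 10% dose threshold passes the
3%/2 mm gamma test (γ ≤ 1), and the average γ is 0.137 — the two "codes"
agree within clinical tolerance.  The survival reports apply the stricter
2%/2 mm criteria to the predicted surviving-fraction profiles of each cell
line, with the same verdict structure.

The per-slice radiobiology of one engine, with run-to-run uncertainties:

```r
summ <- bio_summary(pair$code_a, tabs$SCC)
summ[summ$depth_mm %in% c(10.5, 50.5, 79.5, 85.5),
     c("depth_mm", "dose", "survival", "sigma_survival", "rbe", "gyeq")]
#>  depth_mm   dose survival sigma_survival  rbe   gyeq
#>      10.5 1.1077    0.555       1.24e-03 1.26 1.3982
#>      50.5 2.0012    0.314       1.37e-03 1.27 2.5466
#>      79.5 1.9853    0.379       1.09e-03 1.10 2.1858
#>      85.5 0.0496    0.981       7.16e-05 1.00 0.0496
```

Entrance channel at 10.5 mm (1.1 Gy, survival 0.56), the 2 Gy plateau
between 50.5 and 79.5 mm with survival near 0.31–0.38 and Gy-Eq doses of
2.1–2.5 Gy, and the distal fall-off at 85.5 mm where the dose has collapsed
and survival returns to ~1.

A command-line front end wrapping the same functions lives at
`inst/cli/sobpbio.R` (subcommands `design`, `bio`, `compare`, `pair`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/sobpbio.R", package="sobpbio"))')" \
  design --ion p --plateau 20:30 --prescription 2.0
```

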