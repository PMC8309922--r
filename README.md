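# fingerppg

Monte Carlo simulation of reflectance-mode finger photoplethysmography
(PPG) at 660 and 940 nm, and a full synthetic pipeline for noninvasive
blood-glucose estimation with clinical-accuracy evaluation.

## Who this is for

Biomedical-optics and physiological-sensing researchers who want to

* simulate light transport in a nine-layer heterogeneous finger slab
  (stratum corneum → bone, 5.0 mm) with per-layer absorption built from
  chromophores (water, oxy-/deoxyhemoglobin, melanin, glucose) as functions
  of oxygen saturation and glucose concentration;
* sweep an SpO₂ × glucose grid into a synthetic training table of detected
  intensities;
* train a gradient-boosted tree regressor (learning rate 0.3, depth 6, 100
  trees) mapping (I₆₆₀, I₉₄₀, SpO₂) → glucose; and
* evaluate predictions with regression metrics, Clarke error-grid analysis
  and Bland–Altman statistics — and understand *quantitatively* why the
  glucose absorption signal (relative intensity change ~10⁻⁸–10⁻⁶ over the
  physiological range) is buried under Monte Carlo shot noise.

## The core model

Photon packets are launched normally incident with weight 1 minus the
specular Fresnel loss, random-walk with free paths `l = −ln ξ/(μa+μs)`,
deposit `w·μa/(μa+μs)` per interaction, scatter through Henyey–Greenstein
deflections (`E[cos θ] = g`), undergo unpolarized Fresnel
reflection/refraction at refractive-index interfaces, and are terminated by
Russian roulette (threshold 10⁻⁴, survival 0.1, unbiased). Detection is any
exit through a 0.25 mm-radius aperture on the top surface, 0.4 mm from the
source; intensity = detected weight / launched packets. Energy bookkeeping
closes to < 10⁻⁶ relative. Blood absorption at saturation `s` is
`s·μaHbO + (1−s)·μaHHb + 0.1·εg·cg` (εg in L·mol⁻¹·cm⁻¹, cg in mol/L).

The engine (C++ via Rcpp) and the boosted-tree learner (no gradient-boosting
package exists in this stack, so a deterministic exact-greedy implementation
ships in `src/`) are both seedable and bitwise reproducible.

## Worked example

```r
library(fingerppg)

model  <- default_finger_model()                      # 9 layers, 5.0 mm
state  <- physio_state(sao2 = 0.97, cg_mol_per_l = 5.5e-3)
medium <- build_medium(model, 660, state)             # per-layer mua/mus/g/n

set.seed(1)
run_simulation(model, medium, sim_config(n_launch = 1e4))
#> MC simulation: 10000 launched, 524 detected, intensity 0.0075191, mean path 1.39 mm
```

524 of 10⁴ packets exited inside the detector aperture; their summed weight
per launched packet (0.0075) is the detected intensity and their mean total
path from source to detector is 1.39 mm.

```r
res <- run_synthetic_pipeline(pipeline_config("test", master_seed = 1))
res$metrics
#> MSE 1499  MAE 31.3  RMSE 38.72  R^2 -0.6263  Pearson r -0.1283  (n = 15)
```

That is the honest held-out result of the scaled synthetic experiment
(7 × 11 grid, 10⁴ photons/wavelength/point): chance level, because the
glucose term in the tissue absorption is orders of magnitude below the
Monte Carlo noise floor. The noise-free learner-recovery tests (see
`tests/testthat/`) show the regressor itself is sound.

Diagnostics: `plot_clarke_grid()`, `plot_bland_altman()`; fluence maps via
`sim_config(record_fluence = TRUE)`.

A thin CLI wrapping these functions ships at `inst/exec/fingerppg`
(`model`, `optics`, `simulate`, `build-dataset`, `run`, `evaluate`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the headline synthetic-data evaluation from scratch — full
31 × 51 grid at 10⁴ photons per wavelength per point (~10 min on one CPU),
gradient-boosted regression on a shuffled 80/20 split — and writes the
held-out Pearson's r, R², Clarke zone-A percentage and RMSE (mg/dL) as a
JSON object keyed `t3`–`t6`.
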