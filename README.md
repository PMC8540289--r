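# osmoflux

Analysis of passive water and proton transport across lipid bilayer
membranes, built around the idea that both fluxes pass through transient,
spontaneously formed **lipid pores**.

## The problem and who this is for

Membrane biophysicists measure osmotic water permeability by mixing lipid
vesicles with an osmotically active solution in a stopped-flow instrument and
watching the scattered-light intensity as the vesicles shrink. At low osmotic
pressure differences (tens of mOsm) the kinetics are not the textbook
single-phase decay: the trace first dips while the membrane reorganizes, only
then rises as water flows out. The time to the minimum — the deflection time
`t0` — behaves like a pore-opening delay: it scales as `1/Δπ`, grows with
membrane bending rigidity, and shrinks with temperature. Once pores are open
they also conduct protons, so an imposed pH gradient dissipates faster at
larger osmotic drive.

osmoflux packages the full quantitative chain for this kind of experiment:

* **Core model** — Helfrich bending energy
  `E = ½ κ_b (C₁+C₂−C₀)² + κ_G C₁C₂`, the osmotic bookkeeping of 1:1
  stopped-flow mixing, the empirical delay law
  `t0 = [k + a(κ_b − κ_ref)] · max(0, 1 − b(T − T_ref)) / Δπ`, and the
  Kramers mapping from a pore-opening barrier to a waiting time.
* **Shrinkage simulator** — the delayed osmotic flux law
  `dV/dt = −A·V_w·P·(Δπ − k_mech (V₀−V)/V₀)` for `t ≥ t0` (constant volume
  before), mapped to a three-stage scattered-light trace with dead time and
  noise.
* **Trace fitting** — `fit_trace()` extracts `t0`, the plateau intensities,
  the stage-II slope and the osmotic water permeability `P` (m/s with an
  optical gain calibration, relative units without);
  `fit_delay_law()` and `correlate_delay_rigidity()` perform the run-level
  regressions of `t0` on `1/Δπ` and on `κ_b`.
* **Flicker spectroscopy** — `generate_contours()`, `render_frames()`,
  `extract_contours()` and `fit_bending_rigidity()` implement GUV
  flicker-noise analysis: the equatorial fluctuation spectrum
  `⟨|u_n|²⟩ = B_n(κ_b, σ̄)` from spherical-harmonic equipartition, fitted for
  the bending rigidity with a bootstrap confidence interval.
* **Proton flux** — two-phase fluorescence kinetics of a membrane-bound pH
  probe and the 80–150 s windowed slope that quantifies transmembrane proton
  flux (`simulate_fluorescence()`, `window_slope()`, `flux_response()`).
* **Synthetic data** — `study_design()` plus `make_*_dataset()` generate the
  whole experimental grid (compositions × Δπ × temperature × solute ×
  replicates, flicker stacks, the six-curve proton set) as plain-text,
  bit-reproducible fixture bundles with ground-truth manifests.
* **CLI** — an `osmoflux` script (in `inst/exec/`) with `make-fixtures`,
  `fit`, `flicker`, `proton`, `correlate` and `report` subcommands.

See the vignette (`vignettes/osmoflux-methods.Rmd`) for the models,
estimators, defaults and their rationale.

## Worked example

Predict the pore-opening delay for an egg-PC-like membrane at Δπ = 50 mOsm,
simulate the stopped-flow trace, and recover the parameters:

```r
library(osmoflux)

cond <- osmotic_condition(delta_pi = 50)   # mOsm, from 1:1 mixing
mech <- membrane_mechanics(kappa_b = 25)   # k_BT
t0   <- pore_delay_time(cond, mech)$t0     # 0.04 s

tr  <- simulate_shrinkage_trace(cond, shrinkage_physics(t0 = t0),
                                noise_sd = 0.02, seed = 1)
fit <- fit_trace(tr, optics_gamma = 10)
fit
#> Stopped-flow shrinkage trace fit
#>   status: ok
#>   t0 = 0.03728 s (resolvable)
#>   stage-I drop = 0.7806 a.u., stage-II/III rise = 0.3341 a.u.
#>   stage-II slope = 6.998 a.u./s
#>   permeability = 2.004e-05 (m/s)
```

The fitted `t0` (37 ms) recovers the 40 ms ground truth to within the noise,
and the permeability recovers the simulator's 2×10⁻⁵ m/s. The stage-I drop is
the interface-reorganization signature; the stage-II/III rise
(`γ·Δπ/k_mech = 0.33` a.u. here) measures how far the vesicle shrinks before
the elastic back-pressure balances the osmotic drive.

Bending rigidity from GUV contour fluctuations:

```r
ctr <- generate_contours(10, mech, sigma_bar = 5, n_frames = 2000, seed = 2)
rig <- fit_bending_rigidity(ctr, seed = 3)
rig
#> Flicker-spectroscopy bending rigidity fit
#>   kappa_b = 24.8 kT  (95% CI 24.5-25.1)
#>   sigma_bar = 5.14, modes 2-20, 2000 frames
```

The fitted rigidity recovers the generating `κ_b = 25 k_BT`; `sigma_bar` is
the reduced membrane tension treated as a nuisance parameter.

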