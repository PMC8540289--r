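---
title: "Models and methods behind osmoflux"
author: "osmoflux authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind osmoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmoflux)
```

## The scientific problem

A lipid bilayer is highly permeable to water even though its hydrophobic core
should be a barrier. One proposed resolution is that water crosses through
transient, spontaneously formed hydrophilic *lipid pores*. If that is right,
three things should be observable in a vesicle experiment:

1. when vesicles are abruptly exposed to an osmotic pressure difference
   $\Delta\pi$, the shrinkage should not start immediately — there should be a
   delay $t_0$ while the membrane reorganizes and a pore opens, and that delay
   should shrink as the osmotic drive grows ($t_0 \propto 1/\Delta\pi$);
2. the delay should depend on membrane mechanics: stiffer membranes (higher
   bending rigidity $\kappa_b$) should take longer to open a pore;
3. open water-filled pores should also conduct protons (Grotthuss relay along
   the water chain), so a pH gradient should dissipate faster when the osmotic
   drive — and hence the pore population — is larger.

osmoflux implements the quantitative machinery for all three observations:
a forward model of delayed osmotic shrinkage and its stopped-flow
light-scattering signature, estimators that parameterize measured traces,
flicker-noise spectroscopy for $\kappa_b$ from giant unilamellar vesicle
(GUV) contours, a windowed slope estimator for proton flux, and the two
run-level regressions ($t_0$ vs $1/\Delta\pi$; $t_0$ vs $\kappa_b$). A
synthetic-data layer emulates both instruments so the entire pipeline is
testable end to end with no external data.

## Membrane elasticity

The continuum description is Helfrich's energy per unit area,

$$E = \tfrac{1}{2}\kappa_b\,(C_1 + C_2 - C_0)^2 + \kappa_G\, C_1 C_2,$$

with principal curvatures $C_1, C_2$, spontaneous curvature $C_0$, bending
rigidity $\kappa_b$ and Gaussian modulus $\kappa_G$ (`helfrich_energy_density()`).
We work in $k_BT$ units for the moduli and 1/nm for curvatures. $\kappa_G$
defaults to $-0.8\,\kappa_b$, a common continuum estimate; it never enters the
delay law, because no quantitative $\kappa_G$ dependence is available — only
the energy density uses it.

`barrier_to_delay()` provides the mechanistic reading of the delay: a pore
that must cross an energy barrier $E_p$ opens after a mean waiting time
$\tau_{att}\, e^{E_p/k_BT}$ (Kramers/Arrhenius). Barriers of a few tens of
$k_BT$ with molecular attempt times give macroscopic (millisecond-to-second)
delays, which is what makes the stopped-flow observation possible at all.

## The pore-opening delay law

No first-principles formula links $t_0$ to $(\Delta\pi, \kappa_b, T)$; what is
known empirically is the $1/\Delta\pi$ proportionality, a positive
$\kappa_b$ correlation, and a decrease with temperature. `pore_delay_time()`
therefore uses the simplest separable law consistent with all three trends:

$$t_0 = \big[k + a\,(\kappa_b - \kappa_{ref})\big]\cdot
        \max\!\big(0,\, 1 - b\,(T - T_{ref})\big) / \Delta\pi .$$

Defaults: $k = 2$ mOsm·s at $\kappa_{ref} = 25\,k_BT$ and
$T_{ref} = 298.15$ K, $a = 0.04$ s·mOsm per $k_BT$, $b = 0.01$ per K. The
scale $k$ is chosen so that $t_0$ falls below a 10 ms instrument dead time
whenever $\Delta\pi > 200$ mOsm — the classical high-osmolarity regime in
which the delay is invisible and the plain flux law applies from time zero.
$\Delta\pi = 0$ returns a distinct *infinite delay* outcome (no pore-driven
flux predicted) rather than an error; delays below the dead time are flagged
unresolvable.

Two open modelling questions were settled as follows. First, the delay is
driven by $\Delta\pi$ as a proxy even though the underlying driver may be the
water-activity difference at the interface — the two are not separable at the
osmolalities used, and the experimental axes are in $\Delta\pi$. Second, the
law itself has no intercept in $1/\Delta\pi$, but the fitting side
(`fit_delay_law()`) estimates one anyway, so a nonzero intercept in data
would be detected rather than silently absorbed.

## Osmotic shrinkage dynamics

Water efflux follows the osmotic flux law
$$\frac{dV}{dt} = -A\,V_w\,P\,\Delta\pi,$$
with vesicle surface area $A$, water molar volume $V_w = 0.018$ L/mol and
osmotic water permeability $P$ (m/s). With mOsm read as mol/m$^3$ the
right-hand side is in m$^3$/s without unit juggling. The piecewise (delayed)
model holds the volume constant for $t < t_0$ and integrates the flux law
afterwards.

Two refinements make the trajectory physical:

* **Elastic back-pressure.** The experiment reaches a finite equilibrium set
  by the membrane's resistance to deformation, yet the external osmolality is
  effectively constant. We model the net drive as
  $\Delta\pi - k_{mech}\,(V_0 - V)/V_0$: a linear elastic term that grows with
  relative volume loss. The default $k_{mech} = 1500$ mOsm makes the largest
  experimental difference (150 mOsm) produce a 10% equilibrium volume loss,
  matching the shrinkage magnitude seen by dynamic light scattering. Whether
  the stage-III plateau reflects mechanical balance or water-activity
  equilibration is not experimentally separable; the mechanical reading is
  implemented. $\Delta\pi \ge k_{mech}$ is flagged as a full-collapse regime
  outside the model's validity.
* **Area update.** $A$ follows the sphere law $A \propto V^{2/3}$ as the
  vesicle shrinks; a frozen-area variant is kept (`area_mode = "frozen"`)
  because it has an exact exponential closed form used as a solver check.

Integration uses an adaptive solver (lsoda) at relative tolerance $10^{-8}$
on the reduced volume $v = V/V_0$; the test suite checks it against an
independent fixed-step Euler oracle ($\Delta t = 10^{-5}$ s) to 0.1%.

## From volume to scattered light

The measured signal is scattered-light intensity, which tracks the state of
the membrane interfaces. The trace has three stages: a drop while the outer
interface reorganizes (stage I, duration $t_0$), a rise while water flows out
(stage II), and a final plateau (stage III). `intensity_from_volume()` builds
this anatomy:

* stage I is a cubic ease from the pre-mix level $I_{0,0}$ down to the
  minimum $I_{0,fin}$ with zero slope at both ends — the data constrain only
  the endpoints and the fact that the global minimum marks $t_0$;
* for $t \ge t_0$ intensity is affine in relative volume loss,
  $I = I_{0,fin} + \gamma\,(V_0 - V)/V_0$, following the experimentally
  validated linear correlation between scattered intensity and internal
  volume (no Lorenz–Mie computation is attempted);
* the final plateau is therefore $I_{fin,fin} = I_{0,fin} +
  \gamma\,\Delta\pi/k_{mech}$.

`apply_instrument()` then removes samples before the dead time (default
10 ms) and adds seeded Gaussian noise.

## Trace parameterization

`fit_trace()` bundles four estimators, each exported separately:

* **Deflection time** (`detect_deflection()`): Savitzky–Golay smoothing
  (quadratic, default window 11 samples) locates the global minimum after the
  dead time; because the quadratic smoother is biased toward the flatter
  stage-I side of the kink, the minimum is re-located on the raw trace within
  half a window and refined by a clamped 3-point parabola. A minimum at the
  first retained sample means the delay is below the dead time
  (*unresolvable*); absence of a significant rise after the minimum (flat
  isosmotic control, monotone decay) yields the distinct *no-deflection*
  outcome. Thresholding uses the robust noise scale
  $\mathrm{mad}(\Delta I)/\sqrt{2}$, so detection is invariant to intensity
  offsets.
* **Plateaus** (`extract_plateaus()`): medians of the first 5 samples
  ($I_{0,0}$; a supplied pre-mix reference takes precedence, useful when
  stage I is mostly inside the dead time) and of the final 5% of samples
  ($I_{fin,fin}$); $I_{0,fin}$ is the 3-sample raw average at the deflection
  point. A drifting final window sets a plateau warning. Both
  stage-II/III-rise notations in circulation denote the same quantity; the
  implementation defines exactly one: $I_{fin,fin} - I_{0,fin}$.
* **Stage-II slope** (`stage2_slope()`): ordinary least squares from the
  deflection point to the first *sustained* crossing (3 consecutive smoothed
  samples) of 50% of the stage-II/III rise. The sustained-crossing rule stops
  isolated noise spikes from truncating the window.
* **Permeability** (`permeability_from_slope()`): inverting the flux law
  gives $P = s\,V_0/(c\,\gamma\,A_0\,V_w\,\Delta\pi)$. The factor $c$
  corrects a bias that is otherwise easy to miss: the OLS slope of a
  saturating-exponential recovery measured over its first half-rise is only
  $c_0 = 12\,[(\ln 2/2)(1-e^{-\ln 2}) - 1 + (1+\ln 2)e^{-\ln 2}]/\ln^3 2
  \approx 0.716$ of the initial slope. When the relative equilibrium volume
  loss $\varepsilon = \Delta\pi/k_{mech}$ is known (from the rise and
  $\gamma$), $c$ is computed for the full area-updating model by integrating
  the normalized dynamics $dx/ds = (1-\varepsilon x)^{2/3}(1-x)$; at
  $\varepsilon \to 0$ this reduces to $c_0$. Without a $\gamma$ calibration
  the permeability is reported in relative units and flagged as such, which
  is how flux comparisons across compositions are made.

At the default study conditions the noiseless round trip recovers $t_0$
within one grid step and $P$ within a few percent; at a per-sample
signal-to-noise of 20 the median recovery error over 50 seeds stays within
15%, with an irreducible per-trace spread of roughly 7% coming from the OLS
slope itself.

## Flicker-noise spectroscopy

A quasi-spherical GUV's thermal shape fluctuations are observed as wiggles of
its equatorial contour. Writing the relative radial displacement along the
equator as $u(\phi) = (r(\phi) - R)/R$ and expanding in angular Fourier
modes, the spherical-harmonic equipartition (Faucon/Méléard-type analysis)
projected onto the equator gives

$$\langle |u_n|^2 \rangle = B_n = \sum_{l \ge \max(2, n)}^{l_{max}}
  \frac{2l+1}{4\pi} \frac{(l-n)!}{(l+n)!} \left[P_l^n(0)\right]^2
  \frac{1}{\kappa_b\,(l-1)(l+2)\,[l(l+1) + \bar\sigma]},$$

with $\kappa_b$ in $k_BT$ and the reduced tension
$\bar\sigma = \sigma R^2/\kappa_b$ as nuisance parameter
(`mode_variance()`, cutoff $l_{max} = 30$). Modes $n = 0, 1$ (dilation and
translation) carry no bending energy and are excluded everywhere; asking for
them is an error, not a silent zero.

The generator (`generate_contours()`) draws independent cosine/sine
amplitudes per mode with variance $2B_n$, which reproduces the per-mode mean
squares exactly. Cross-mode correlations induced by shared spherical-harmonic
degree are not reproduced; the estimator uses only per-mode mean squares, so
this does not affect parameter recovery. Frames are treated as statistically
independent — the camera's finite frame rate and the resulting temporal
autocorrelation are not modelled.

The estimator (`fit_bending_rigidity()`) computes per-frame Fourier
amplitudes of $u$ (per-frame mean radius removes the monopole), averages
their squared moduli per mode over usable frames, and fits
$(\kappa_b, \bar\sigma)$ by least squares of $\log\langle|u_n|^2\rangle$
against $\log B_n$ over modes 2–20 by default. Because $\kappa_b$ enters the
log spectrum as an additive constant it is profiled out in closed form and
only $\bar\sigma$ needs a one-dimensional search (parameterized as
$e^x - 1$ on $x \in [0, 10]$, i.e. $\bar\sigma$ up to $\sim 2\times 10^4$).
The fitted mode range and tension handling are configurable since no
standard choice exists; free $\bar\sigma$ with $n = 2..20$ is the default.
The 95% confidence interval comes from a seeded frame-level bootstrap
(1000 resamples by default). An exact internal consistency property:
scaling all displacements by $\sqrt2$ halves the fitted $\kappa_b$ and
leaves $\bar\sigma$ unchanged.

### Synthetic microscopy

`render_frames()` draws each contour as a fluorescent ridge with Gaussian
radial cross-section (default $\sigma = 2$ px at the 0.102 µm pixel size of
the emulated camera) over a dark background with Poisson shot noise.
`extract_contour()` walks rays from the vesicle centre, samples the radial
intensity profile by bilinear interpolation at 0.5 px steps, takes the
profile maximum above a robust threshold and refines it with a
baseline-subtracted intensity centroid over a ±5 px window. The centroid was
chosen over the more common 3-point parabola deliberately: bilinear
reconstruction scallops the profile along oblique rays and can displace its
maximum by up to ~0.4 px, while the centroid averages the artifact out to
~0.02 px on noiseless frames.

A frame is rejected — flagged, never an error — when any ray lacks a peak
above threshold or the contour fails closure (neighbouring radius jump above
3 px). The default noise model adds a per-frame dropout artifact (probability
0.25, a 30° sector dimmed to 2% ridge intensity) emulating out-of-focus or
poorly labelled frames; dropout frames fail extraction deterministically, so
the usable fraction is close to 75%, mirroring the fraction of frames that
survives contour extraction in a real acquisition (about 7 500 of 10 000).

The test suite exercises parameter recovery at 7 500 generated contour
frames (within 10%) and the full render→extract→fit path at 500–2 000
rendered frames (within 15%); these sizes keep the suite fast while leaving
the estimator's frame-count consistency checkable (median error decreasing
over 500/2 000/7 500 frames).

## Proton flux through water-filled pores

The pH probe (a fluorescein-labelled lipid) sits in both leaflets, so a pH
jump produces two kinetics: a fast exponential from (de)protonation of the
outer-leaflet dyes and a slow linear rise as protons cross the bilayer,

$$F(t) = f_0 + a_{fast}\,\tfrac{\Delta pH}{1.4}\,(1 - e^{-t/\tau_{fast}})
        + m_{slow}\, t .$$

The slow slope is coupled linearly to the osmotic drive,
$m_{slow} = s_{ref}\,\Delta pH\,(g_0 + c_\pi\,\Delta\pi)$, with a positive
baseline $g_0$ (pores open occasionally even without osmotic drive) and gain
$c_\pi = 0.02$ per mOsm, so the 150 mOsm condition carries four times the
zero-drive flux. Only the monotone trend is a measured claim; the linear form
is the simplest coupling carrying it. Grotthuss relay itself is not
simulated — it is the mechanistic reason a water-filled pore conducts
protons, and it motivates tying $m_{slow}$ to the same pore population that
carries the water flux. The probe's pH response is absorbed into $a_{fast}$
and $s_{ref}$ (linear over the 1.4-unit range used; no titration curve).

`window_slope()` estimates $m_{slow}$ by OLS over 80–150 s, after the fast
phase (default $\tau_{fast} = 5$ s) has fully decayed; the estimate is then
invariant to $f_0$ and to the fast amplitude for any $\tau_{fast}
\lesssim 10$ s. A control with $\Delta pH = 0$ but nonzero $\Delta\pi$
carries a small osmotic artifact (a fast-saturating bump plus a linear term
at 3% of the corresponding pH-driven slope), kept under the 5% bound
established for that control; it can be disabled to verify the zero-slope
null. `classify_photobleaching()` applies the long-time criterion that a
drift producing under 3% baseline change in 3 hours is negligible.
`flux_response()` sorts windowed slopes by $\Delta\pi$ and reports whether
the flux is non-decreasing.

## The synthetic study design

`study_design()` fixes the emulated experimental grid: compositions PC,
PC/chol 7:3, PC/lysoPC 7:3 and PC/PE 7:3; $\Delta\pi \in \{15, 25, 50, 100,
150\}$ mOsm (the range reachable by 1:1 mixing of a ~10 mOsm suspension with
30–300 mOsm stocks, `delta_pi_from_mixing()`); three replicates; a 110 nm
mean-diameter vesicle; 10 000 flicker frames per composition. The default
bending rigidities (25, 50, 15, 25 $k_BT$) and effect multipliers (PE: 1.2×
permeability; cholesterol: 10× stage-II/III optical rise) are package
defaults encoding the qualitative composition effects — cholesterol stiffens
and lysoPC softens the membrane, PE slightly raises water flux — and are
labelled as defaults, not measurements, in every manifest. The `"ci"` profile
(3 osmotic differences, 1 replicate, 500 frames) regenerates the whole bundle
in seconds.

Per-file seeds derive deterministically from the master seed and the
condition label, with the solute label deliberately excluded: the identity of
the osmotically active compound (KCl, NaCl, sucrose) never enters any
computation, so runs differing only in solute are bit-identical — the
package-level encoding of the observation that the deflection position
depends on osmolality, not chemistry.

All fixture files are delimited text with `#`-keyed metadata headers written
at 17 significant digits, so write∘read is a byte-identical round trip and
bundles are hashable.

## Numerical choices and degenerate inputs

* ODE tolerance $10^{-8}$ (relative); reduced-volume state keeps the solver
  well scaled at vesicle volumes of $10^{-22}$ m$^3$.
* Smoothing window 11 samples (11 ms at the default 1 kHz sampling), odd by
  construction; windows shorter than 3 are rejected.
* Peak-finding tie-break in extraction is "first" (deterministic).
* $\Delta\pi = 0$: infinite delay (core model), flat trace (simulator),
  no-deflection outcome (fitting), undefined permeability (error).
* Monotonically decreasing traces (no recovery) are a no-deflection outcome,
  not an error; blank or defective frames are rejected frames, not errors.
* Insufficient data (fewer than 2 distinct $\Delta\pi$, fewer than 3
  rigidity pairs, fewer than 100 usable frames, stage-II window under 5
  samples) raises a typed insufficient-data error.

## Limitations

* The delay law is empirical; its separable form and the linear temperature
  attenuation are the simplest choices consistent with the observed trends,
  not derived dynamics.
* One representative vesicle stands in for the population: no size
  polydispersity, no multi-exponential population fitting.
* The optics map is affine; refractive-index physics is out of scope.
* Flicker frames are independent and free of illumination gradients and
  focus drift; real acquisitions need temporal-correlation and flat-field
  corrections before these estimators apply quantitatively.
* Absolute permeability requires the optical gain calibration $\gamma$;
  without it all $P$ values are relative, exactly as flagged.
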