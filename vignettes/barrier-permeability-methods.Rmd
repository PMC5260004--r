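---
title: "Modeling and estimating barrier permeability on two-compartment chips"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and estimating barrier permeability on two-compartment chips}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barrierkin)
```

## The assay and the model

A two-compartment microfluidic barrier chip consists of an outer channel,
perfused with medium and lined with endothelial cells, and a central
compartment holding astrocytes (BBB configuration) or tumor cells (BTB
configuration). The two are separated by a porous interface (3 µm pores)
through which solute exchanges. A fluorescent tracer is perfused at
0.1 µL min⁻¹ for 90 min and frames are acquired every 2 min; the analysis
question is how fast tracer accumulates on the "brain" side relative to the
"vascular" side.

`barrierkin` models both compartments as well mixed. With `C_PF` and `C_CC`
the outer and central concentrations (arbitrary fluorescence units), the
mass balance is

$$\frac{dC_{PF}}{dt} = \frac{Q}{V_{PF}}(C_{in} - C_{PF})
  - \frac{PS}{V_{PF}}(C_{PF} - C_{CC}) + \frac{E}{V_{PF}}C_{CC},$$
$$\frac{dC_{CC}}{dt} = \frac{PS}{V_{CC}}(C_{PF} - C_{CC})
  - \frac{E}{V_{CC}}C_{CC},$$

where `PS` (nL min⁻¹) is the permeability–surface-area exchange
coefficient, and `E = CL_eff (1 − I)` is the effective efflux clearance,
active only for transporter substrates (`I` is the inhibition fraction:
0 untreated, 1 under maximal inhibition). Efflux returns tracer from the
central compartment to the lumen, so the system conserves mass when `Q = 0`.
The equations are integrated with `deSolve::lsoda` at absolute and relative
tolerance $10^{-10}$ and sampled at the frame times.

**Key simplification.** The measured quantity is an ROI *sum*, which
integrates over space, so a well-mixed (non-spatial) model is used. Real
chips show fluorescence gradients along the channel; one consequence,
discussed under *Limitations*, is that the ratio statistic saturates in this
model in a way the spatially extended device need not.

**Efflux is linear.** Clearance × concentration, not Michaelis–Menten: no
saturation data are available for this assay, and linearity keeps an
analytic solution available (`closed_form_central()`, the constant-lumen
limit used as the simulator's test oracle).

**Inlet is a step.** The tracer syringe is connected at perfusion start.
For cohort generation the frame clock starts when the tracer front reaches
the imaging field: the outer channel fills convectively (plug flow, one
channel volume in `V_PF/Q` = 2 min) rather than by exponential mixing, so
the lumen is initialized at the inlet concentration
(`outer_conc0 = inlet_concentration`). Without this, the first frames are
background-dominated and the ratio series starts with a spurious transient
that no real chip shows.

## The k_in estimator

Per frame, the ROI sums form `y(t) = (s_central + s_outer)/s_outer`, and
`k_in` is the OLS slope of `y` on `t` (min⁻¹, displayed × 10⁻³), with
intercept `O_C`. Although the assay literature defines the numerator
intensity "at the end of perfusion", a regression over time is only
meaningful with per-frame values for both compartments; that reading is
used here.

Two further conventions:

* **Units.** The slope of a dimensionless ratio against minutes is min⁻¹.
  Assay reports sometimes print µL min⁻¹ for this quantity; that unit is
  not dimensionally consistent with the ratio regression and is not used.
* **Fold changes.** Fold change is computed as the ratio of group means.
  Published prose for this assay quotes fold changes ("14-fold",
  "eight-fold") that do not equal the ratios of the printed group means;
  `fold_change()` always reports the computed ratio.

**Linear-zone selection.** Under a tight barrier the ratio stays linear
over the full 90 min and `zone = "full"` (the default) fits everything. In
saturating conditions — cell-free chips, efflux-inhibited runs — uptake
bends as `C_CC` approaches `C_PF` (the ratio is bounded by 2 without
efflux), and `zone = "auto"` selects the window: among all windows starting
at the first frame with at least `min_points` (default 10) frames, it
maximizes adjusted R², preferring the longest window on ties. On noiseless
concave series this picks the shortest window (any extension adds
curvature); under noise, short windows are penalized by their noise and the
selection moves to the longest stretch that is still linear. Frames with
non-positive outer signal (possible after background subtraction) are
dropped, never clamped.

**Background.** The background ROI is used as a significance check
(`background_assessment()`: per-pixel compartment mean over the final
quartile of frames must strictly exceed the background per-pixel mean + 3
SD), not subtracted by default — matching assay practice. With the
simulator's default autofluorescence (10 au/pixel against a 10 au/pixel
plateau signal) unsubtracted background attenuates the fitted slope by a
factor `gC_in/(gC_in + b)`; cohort-level analyses in this package therefore
use `background_mode = "subtract"` (per-pixel background mean × region
pixel count, floored at zero) when absolute magnitudes matter. Ordering and
significance between groups are unaffected by the choice, since the
attenuation is common to all groups.

## Synthetic data: what it emulates, and what it does not

No raw stacks were deposited for this assay, so the generator stands in for
them:

* **Geometry** (`default_geometry()`): the device's channel dimensions are
  proprietary, so an explicitly documented idealization is used — a
  200 × 100 µm channel, 10 mm long (`V_PF` = 200 nL), `V_CC` = 200 nL, and
  1350 pores of 3 µm diameter through a 50 µm wall. The pore dimensions
  were chosen so that the pore-limited free-diffusion coefficient
  `PS = D·A/L` of a ~0.6 kDa dye (`unrestricted_ps()`) matches the
  calibrated cell-free preset (~4.5 nL min⁻¹). Every dimension is
  configurable.
* **Diffusion coefficients**: Stokes–Einstein-style scaling
  `D = 400 (600/MW)^{1/3}` µm² s⁻¹. This treats molecules as compact
  spheres; it understates the hydrodynamic radius of flexible dextrans, so
  measured values should be supplied for polymers when available.
* **Barrier presets** (`condition_preset()`): passive `PS` values are set
  by the early-uptake identity `PS = k_in × V_CC` at the assay's reported
  group-mean rates (e.g. BBB free Texas Red 2.5 × 10⁻³ min⁻¹ → 0.50
  nL min⁻¹). Efflux clearances (BBB 155.6, BTB 28.82 nL min⁻¹) were
  root-found once so that the linear-zone fitted control (`I = 0`) rate on
  noiseless traces matches the reported rhodamine 123 control means, with
  `PS` fixed by the fully inhibited group. Verapamil and cyclosporine A
  both map to `I = 1` (reported concentrations ensured maximal inhibition),
  so the two inhibitors are indistinguishable in the model; intermediate
  `I` is allowed.
* **Imaging** (`imaging_model()`): expected pixel value
  `gain·C + background`; Poisson shot noise on the expectation, then
  additive Gaussian read noise (SD 2 au). Defaults (gain 0.1 au per
  concentration-au per pixel, background 10 au) give an ROI-sum SNR ≈ 20 at
  the BBB-preset plateau, and keep the background expectation high enough
  that clamping at zero is negligible (< 10⁻³ au per pixel), so ROI-sum
  means remain unbiased. Frames are doubles in memory and are quantized to
  16-bit only on write. The default ROI layout gives the outer and central
  regions identical pixel counts, so the intensity ratio estimates the
  concentration ratio directly.
* **Replicate structure** (`cohort_spec()`): chip-to-chip variability
  enters only through `PS`, drawn lognormally with mean at the preset and
  CV 0.3 — the scale implied by the assay's reported SEMs
  (SEM/mean × √n ≈ 0.29–0.33 across groups). Per-chip seeds derive from
  the master seed by counter-based splitting
  (`seed + 1000003·chip_index mod 2³¹−1`), making cohorts byte-reproducible.
* **Not emulated**: brightfield frames, cell morphology, photobleaching,
  spatial gradients within compartments, the culture-phase flow ramp, and
  focal drift or registration errors. Tests passing on this generator show
  the *analysis* is correct and calibrated; they do not show the well-mixed
  model reproduces every feature of real chips.

## Numerical choices and degenerate inputs

* ODE tolerances $10^{-10}$; trajectories that go negative beyond
  $-10^{-8}$ raise an error naming the offending parameters, tiny negative
  round-off is clamped to zero.
* `closed_form_central()` returns 0 for all t when `PS = E = 0` (documented
  convention rather than 0/0).
* OLS is computed in closed form (centered normal equations); a constant
  series returns slope 0 with `R² = NA`; a window with zero time-variance
  is an error.
* Adjusted-R² ties in `linear_zone(..., "auto")` are resolved to the
  longest window (tolerance 10⁻¹²); a series with no linear signal anywhere
  falls back to the full series.
* Zero-variance groups in `compare_groups()` produce `NA` statistics
  flagged `indeterminate`, never exceptions; the variance F test always
  places the larger sample variance in the numerator and is two-sided.
* `background_assessment()` with zero background variance and equal means
  reports `indeterminate`, not failure.

## The shear-stress operation

`wall_shear_stress()` implements the wide-channel parallel-plate formula
τ = 6µQ/(wh²) (default viscosity 0.7 cP, culture medium at 37 °C). With the
idealized default geometry and 0.1 µL min⁻¹ it evaluates to
3.5 × 10⁻² dynes cm⁻²; published shear figures for such devices depend on
the proprietary channel dimensions, so no particular printed value is
asserted — the operation is generic and unit-checked against an independent
SI conversion in the tests.

## Problem sizes used by the tests

The suite runs entirely on generated data: unit fixtures use 32 × 48 px
frames and 10–46 frame series; calibration checks use 500 replicate fits
(estimator unbiasedness), 150–200 render seeds (noise-model mean/variance),
1000 null simulations (Welch type-I error), and 50 independent cohorts of
3 groups × 6 chips (end-to-end ordering and significance). These sizes give
Monte-Carlo standard errors comfortably inside the asserted bounds while
keeping the suite fast.

## Known limitations

* In a well-mixed two-compartment model the ratio `y = 1 + C_CC/C_PF`
  cannot exceed 2 without efflux, so a 90-min series cannot sustain slopes
  near the fastest reported rates (~23 × 10⁻³ min⁻¹) over the whole run;
  such rates exist only as early-window slopes, and linear-zone fits of the
  fast presets land 10–20% below their nominal calibration targets. A 1-D
  spatially extended lumen could relax this; it is deliberately out of
  scope.
* Because the efflux model acts on the central compartment, the *initial*
  uptake slope is independent of `E`; low control rates arise through early
  saturation. Window selection therefore matters more for efflux substrates
  than for passive tracers, and noisy control fits scatter widely — as do
  the assay's own reported control SEMs.
* `k_in` is a relative, geometry-dependent rate; no conversion to an
  absolute permeability coefficient (cm s⁻¹) is attempted.
* Welch pairwise tests are reported without multiple-comparison adjustment
  (only Tukey HSD adjusts), matching assay practice; treat the pairwise
  Welch p values accordingly.
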