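---
title: "Methods: analytic beam models, gamma comparison and dosimetric metrics"
author: "beamqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analytic beam models, gamma comparison and dosimetric metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beamqa)
```

## Scope

`beamqa` implements the standard quality-assurance analyses of external-beam
radiotherapy dosimetry — the gamma index, percentage-depth-dose (PDD)
metrics, lateral-profile metrics and relative dosimetric factors — together
with an analytic photon-beam simulator that stands in for Monte Carlo or
measured dose data. The simulator exists so that every analysis routine can
be exercised, cross-checked and regression-tested on data with known ground
truth; it is explicitly *not* a radiation transport model, and nothing in it
should be mistaken for machine commissioning data.

## The analytic beam model

### Depth dose

The central-axis dose at depth $z$ (cm) is modelled as

$$D(z) \propto \left(1 - e^{-k z}\right) e^{-\mu z}
  \left(1 + s\,(A - 10)\right),$$

a build-up term with rate constant $k$ (per cm), an effective exponential
fall-off with coefficient $\mu$ (per cm), and a small linear output
multiplier in the square field side $A$ (cm) with slope $s$ per cm relative
to the 10 × 10 cm² reference. The product form has a closed-form depth of
maximum dose,

$$z^* = \frac{1}{k}\,\ln\!\left(1 + \frac{k}{\mu}\right),$$

which the test suite uses as an independent oracle for the `find_dmax`
search. Noiseless curves are scaled so the maximum is exactly 100.

**Calibration.** The two presets are calibrated to the standard clinical
anchors of megavoltage beams from a linac at SSD 100 cm: the depth of
maximum dose (1.4 cm at 6 MV, 2.5 cm at 12 MV) and the beam-quality index
D20/D5 (0.415 at 6 MV, 0.497 at 12 MV for a 10 × 10 cm² field). Because the
model folds inverse-square divergence and phantom scatter into a single
exponential, $\mu$ is an *effective* fall-off coefficient obtained as
$\mu = -\ln(D20/D5)/15\,\mathrm{cm}$ — about 0.0586/cm at 6 MV — rather than
a narrow-beam attenuation coefficient (≈ 0.046/cm at 6 MV), which would
understate the fall-off once divergence is omitted. $k$ is then solved
numerically from the closed form so that $z^*$ lands on the calibrated
depth. A consequence worth knowing: the model reproduces the *ratio* D20/D5
faithfully but sits a few percent below typical measured PDD values at
intermediate depths, because the single-exponential shape is slightly too
steep between $z^*$ and 20 cm. The analyses here only ever consume
normalized shapes and ratios, so this is acceptable by design.

### Lateral profiles

Profiles at depth $z$ are a difference of standard normal CDFs at the two
projected field edges (half-width $w/2$ with
$w = 10 A\,(\mathrm{SSD}+z)/\mathrm{SSD}$ mm), an in-field "horn" factor
$1 + a\,(2x/w)^2$ that shapes flatness, and, when a wedge gradient $g$
(per cm) is set, a transmission factor $e^{-g\,(x + w/2)/10}$ anchored at
the thin edge of the field. The edge width parameter `penumbra_sigma`
(σ, mm) maps to the 80%–20% penumbra through the closed form
$2\sqrt{2}\,\mathrm{erf}^{-1}(0.6)\,\sigma \approx 1.683\,\sigma$; the
defaults (3.2 mm at 6 MV, 4.5 mm at 12 MV) put the penumbra in the 5–8 mm
range typical of measured profiles at 10 cm depth. The default horn
amplitude 0.08 yields flatness a little above 105%, matching the
$D_{max}/D_{min}$ convention's typical magnitude.

Anchoring the wedge at the thin field edge (rather than at the axis) makes
central-axis wedge factors come out below 1 and decrease with the gradient,
as a transmission argument requires. One divergence from measured behaviour
is documented and deliberate: physical wedge factors *increase* with field
size (wedge scatter), while this pure-transmission model has them decrease,
because a larger field puts more wedge material over the axis. The factor
operations themselves are agnostic — they are ratios of whatever readings
they are given.

### 3-D grids, perturbations and noise

`make_dose_grid` builds a separable product
$\mathrm{pdd}(z) \cdot \mathrm{profile}(x;z) \cdot \mathrm{profile}(y;z)$,
adequate for exercising grid analyses but without any cross-axis scatter
coupling. `perturb_grid` provides the controlled deviations the gamma
engine is tested against: per-axis shifts (linear resampling, edge values
held), global rescaling and noise. Noise everywhere is multiplicative
Gaussian with relative standard deviation `noise_sd`, applied under a
private seeded RNG stream (the session RNG is untouched); this mimics the
way Monte Carlo statistical uncertainty scales with local dose, but not its
spatial correlation or its dependence on voxel volume and history count.
Doses are clipped at zero.

What passing tests on these synthetic data do show: the analysis code
computes its metrics correctly on data of the stated structure, at the
stated noise levels, with known answers. What they do not show: anything
about a specific accelerator, detector effects (volume averaging, energy
response), heterogeneous media, or transport physics.

## The gamma engine

For a reference point $r$ with dose $D_r$, the gamma index against an
evaluated distribution $D_e$ is

$$\gamma(r) = \min_{e} \sqrt{\frac{|e - r|^2}{r_m^2}
  + \frac{\left(D_e(e) - D_r\right)^2}{\Delta D_m^2}},$$

with $r_m$ the distance-to-agreement criterion (default 3 mm) and
$\Delta D_m$ the dose criterion (default 3%). Conventions the literature
often leaves implicit are explicit configuration here:

* **Normalization** — `"global"` (default): $\Delta D_m$ is a percentage of
  the global reference maximum, the standard clinical 3%/3mm practice;
  `"local"`: a percentage of each reference point's own dose, which is
  stricter in low-dose regions and undefined at zero-dose points (an
  error).
* **Dose threshold** — reference points below `dose_threshold_percent` of
  the global maximum are excluded; the default is 0 (no cutoff).
* **Search window** — `search_limit_factor` × $r_m$ (default 3×); any
  minimum beyond it would have $\gamma > 3$ anyway.
* **Direction** — fixed reference → evaluated; gamma is not symmetric and
  reports state the direction.

**The minimum is taken over the continuous piecewise-linear interpolant**
of the evaluated distribution, not over its samples. In 1-D the per-segment
minimum of $\gamma^2$ (a quadratic on each linear dose segment) is solved
in closed form, so the result is exact up to floating point. In 2-D/3-D the
engine scans candidates at `interp_step_mm` spacing (default $r_m/10$)
inside the window — including the evaluated grid nodes and the reference
position itself — and refines the best basins by a pattern search on the
multilinear interpolant down to a 10⁻⁹ mm scale. `interp_step_mm` therefore
controls basin-finding density, not final accuracy. Evaluated sample
positions are candidates explicitly, so identical distributions give
$\gamma = 0$ exactly.

`gamma_oracle` is a deliberately different implementation used for
verification: an exhaustive, unwindowed dense scan at `interp_step_mm`/5,
then multi-level full-grid box scans (shrinking boxes recentered on the
running minimum) around the best spatially-separated candidate basins,
tracking several near-tied sub-minima per level. The suite requires engine
and oracle to agree within 10⁻⁶ across randomized 1-D and 2-D cases; the
two implementations share only the interpolant definition. Numerical
niceties discovered en route and handled: refinement must start from
several seed basins (a coarse scan can rank two basins in the wrong order
near ties), refinement boxes must span the seed-separation scale rather
than the dense-scan step, each zoom level must keep at least two sample
spacings of coverage so the minimum cannot escape the next box, and
descent-style polish stalls on interpolation kinks and anisotropic curved
valleys where exhaustive box scans do not.

Binned agreement follows the conventional thresholds: excellent
$\gamma \le 0.5$, good $0.5 < \gamma < 1$, poor $\gamma \ge 1$; the passing
rate counts $\gamma < 1$ strictly.

## PDD and profile metrics

* **`find_dmax`** takes the maximum sample (ties to the smallest depth),
  refines by a parabola through the maximum and its neighbours when the
  maximum is interior and not on a plateau, and snaps the result to the
  grid resolution. Plateaus skip refinement — on a flat top the parabola
  midpoint would be an artifact of the plateau edges, and the shallow edge
  is the conventional report.
* **`normalize_pdd`** divides by the maximum *sampled* dose, so normalized
  curves have a maximum of exactly 100 (using the off-grid parabola peak
  would leave it slightly below). Curves already flagged normalized pass
  through unchanged, which lets partial scans reconstructed from published
  PDD tables (whose maximum sample is below 100 because the build-up region
  is not tabulated) keep their tabulated values.
* **`pdd_summary`** interpolates PDD at 5/10/20 cm linearly and forms
  D20/D5; values are stored unrounded and rounded only in report
  formatting (ratios to 3 decimals, percentages to 1–2, penumbra to 2,
  matching the usual table precision).
* **Field width** is defined by the 50%-of-central-axis-dose crossings —
  the standard convention — because "central 80% of the field width" needs
  a width definition. All crossings interpolate linearly between adjacent
  samples and, when a noisy profile crosses a level more than once, the
  crossing nearest the axis wins.
* **Flatness** is $D_{max}/D_{min} \times 100$ over the central 80% region.
  The alternative "difference over sum" definition appears in parts of the
  literature describing the same quantity; the ratio form is used here
  because typical reported values slightly above 100% are only consistent
  with the ratio convention. **Symmetry** is the worst mirrored point-pair
  ratio in the central region, oriented ≥ 100%, with the mirror dose
  obtained by linear interpolation — a pointwise definition aggregated by
  worst case, again consistent with reported values barely above 100%.
* **Geometric penumbra** is the projection formula
  $P = s\,(\mathrm{SSD} + d - \mathrm{SDD})/\mathrm{SDD}$ for source size
  $s$; it vanishes when the dose plane sits at the diaphragm distance.

## Relative dosimetric factors

`scp_factor`, `sc_factor` and `wedge_factor` are pure checked ratios —
multiplying both readings by any constant leaves them unchanged, and
non-positive readings are errors. `model_factor_table` generates synthetic
factor sweeps from the beam model: S_cp as the central-axis dose ratio at
the reference depth (10 cm) to the 10 × 10 cm² field of the same energy
(so the reference row is exactly 1), and S_c under the stated convention
that head scatter contributes 35% of the total output variation with field
size. The default `scatter_slope` of 0.007 per cm keeps a 1–40 cm S_cp
sweep monotone and inside the published 0.55–1.22 range of phantom output
factors; a single linear slope cannot *also* reproduce the steep small-field
drop toward 0.55 itself, which would need a saturating scatter model — a
known limitation accepted to keep the generator minimal.

## File formats

The text dose-grid dialect (one `#axis name unit n values…` header per
axis, then one value per line, x varying fastest) and the two-column scan
CSV both serialize doses with 17 significant digits, so write/read
round-trips are value-exact and the files diff cleanly. The DICOM RT Dose
importer handles uncompressed little-endian files (explicit or implicit
VR), applies the dose-grid scaling factor, and converts patient-space mm to
the package convention (x, y in mm; z in cm); undefined-length elements,
compressed transfer syntaxes and non-uniform frame spacings are rejected as
unsupported rather than guessed at. Import only: the analyses consume dose
data, they never emit DICOM.

## Problem sizes and tolerances used in validation

The test suite runs on 301-point depth-dose curves (0–30 cm at 0.1 cm),
profiles at 0.1–1 mm sampling, and 2-D grids of 10–16 nodes per side at
2–2.2 mm spacing — sizes chosen so the brute-force gamma oracle remains
exhaustive while the full suite stays quick. Equality tolerances follow the
quantity: exact (`identical`) for normalization anchors, seeds and
round-trips; 10⁻⁶ for engine/oracle gamma agreement; 1% for penumbra
closed forms (finite sampling of the error function); one grid step for
d_max recovery. Axis uniformity is checked to 10⁻⁹ relative; profile
evenness of the symmetric generator holds to 10⁻¹².

## Known limitations

* The beam model is separable and effective: no inverse-square term, no
  scatter kernel, no electron contamination in the build-up region, no
  off-axis softening. It targets *shape realism sufficient to exercise the
  analyses*, not dosimetric truth.
* The wedge model's field-size trend is opposite to physical wedges (see
  above).
* Gamma cost grows with the candidate count; 3-D grids are practical at
  coarser `interp_step_mm` (the refinement stage restores accuracy), but
  there is deliberately no approximate-nearest-neighbour or GPU path.
* `gamma_oracle` is quadratic-cost by design and guarded by a reference
  point limit; it is a verification tool, not an analysis tool.
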