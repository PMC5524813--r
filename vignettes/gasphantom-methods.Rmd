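---
title: "Modelling dissolved gas and bubbles in a cellular tissue phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dissolved gas and bubbles in a cellular tissue phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The system being modelled

A cylindrical type-I collagen hydrogel ("tissue phantom", ~5.5 mm radius,
~5.3 mm tall, seeded with dermal fibroblasts) sits either in a culture well
(during oxygen monitoring) or in a small hyperbaric chamber (during a
simulated dive). Decompression sickness research needs a controllable
3D model in which bubble nucleation, growth and the cellular consequences
can be watched in real time; this package re-implements the computational
side of such a system: the dissolved-gas physics, the virtual oxygen probe,
the bubble image analysis, the growth-curve statistics, and the viability
bookkeeping, plus seeded synthetic-data generators so every stage is
testable without the (undeposited) raw imaging data.

# Dissolved-gas transport model

Each gas `g` dissolves according to Henry's law, `C = k_h * pp`, so partial
pressure (mmHg) is used as the state variable throughout. Oxygen obeys a
reaction-diffusion equation with a Michaelis-Menten sink for cellular
consumption,

    d(ppO2)/dt = D * laplacian(ppO2) - V_max * ppO2 / (ppO2 + K_m) * sigma / k_h,

and nitrogen diffuses identically with `V_max = 0`. The species are
uncoupled (each sink depends only on its own field), which the solver
exploits by marching them independently. Total tissue tension - the driving
force for bubble nucleation - is the sum of the two partial pressures.

Parameters, their units and defaults:

| parameter | meaning | default | unit |
|---|---|---|---|
| `D` (O2) | diffusion coefficient in the gel | 2.5e-9 | m^2/s |
| `D` (N2) | idem | 2.0e-9 | m^2/s |
| `V_max` | max consumption per cell | 3e-17 | mol/cell/s |
| `K_m` | half-maximal ppO2 | 5.6 | mmHg |
| `sigma` | seeding density | 5e3-5e5 | cells/ml |
| `k_h` (O2) | Henry constant | 1.3e-3 | mol/m^3/mmHg |
| `k_h` (N2) | idem | 7.2e-4 | mol/m^3/mmHg |

The kinetic constants are the monitoring-experiment values; the Henry
constants and the N2 diffusivity are aqueous values at 37 degC (the gel is
>95% water) and are deliberate, overridable config defaults - solubilities
in culture medium would differ by a few percent. CO2, although ~20-fold
more soluble than O2 (the basis of the physiological "oxygen window"), is
not transported; its constant appears only in documentation.

# Numerical scheme

The cylinder is voxelised on a Cartesian lattice (spacing `dh`, default
0.17 mm; the bundled analyses and acceptance runs use 0.34 mm, which
resolves the phantom with ~16k voxels) by a voxel-centre inclusion test.
Time marching uses the Barakat-Clark alternating-direction-explicit (ADE)
scheme: two Saul'yev sweeps per step, one traversing indices in increasing
order (so already-updated upstream neighbours enter the stencil), one in
decreasing order, averaged. Pairing each explicit neighbour term with an
implicit centre term makes the scheme unconditionally stable while staying
explicit to evaluate, which is what permits the large operating step
`dt = 2 s` (lambda = D dt/dh^2 is ~0.17 at 0.17 mm).

Boundary handling, face by face (base / vertical sides / top):

* *no-flux*: mirrored ghost equal to the centre value at the sweep's time
  level - monitoring uses this on base and sides (well plastic), the dive
  on the base only;
* *Dirichlet*: ghost extrapolated as `2*pp_b - u`, which pins the boundary
  value on the voxel *face* to second order. The top Dirichlet value is the
  ambient partial pressure (the thin media layer above the gel is assumed
  instantaneously equilibrated and is not meshed); during a dive the value
  follows the chamber profile at every step.

The consumption sink is handled by operator splitting: diffusion step, then
an explicit sink update evaluated on the pre-step field, then a clamp at
zero. Initial conditions are equilibrium with ambient pressure
(`pp = mole_fraction * P_total` per species), and the dive simulation's
initial state is, exactly and by construction, the final state of the 8 h
monitoring simulation.

Two numerical properties deserve explicit statement:

* **Accuracy.** Against a forward-Euler (FTCS) reference at a 100x finer
  step, the ADE solution agrees to ~3e-5 of the field range on small
  instances; a 1D column with a saturated (zero-order) sink matches the
  closed-form parabolic profile `pp_top - q(L^2 - s^2)/2D` (s = height
  above the base) to ~0.02%.
* **Mass conservation.** The averaged-sweep ADE scheme is consistent but
  *not exactly* conservative: with all faces sealed the lattice sum drifts
  by O(lambda^2) per 1000 steps, the drift growing with the field's
  spatial asymmetry (smooth physical fields at the operating step: ~1e-7
  relative; deliberately rough random fields at lambda = 0.125: ~1e-4).
  The test suite verifies both the ~1e-7 figure on a physically generated
  field and the second-order decay of the drift under step refinement.

# The virtual probe experiment

The monitoring experiment inserts a fluorescent O2 probe into the phantom
centre and samples every 80 s for 8 h. Its virtual counterpart averages the
simulated O2 field over a small cylindrical sensor window (default 0.25 mm
radius x 0.5 mm, centred - the physical window size is not documented, so
it is config-exposed; on lattices coarser than the window the nearest voxel
is used) and repeats the simulation three times per density with the cell
density drawn uniformly within +/-10% of nominal from a seeded generator,
reporting the per-time mean and sd. At 8 h the three densities separate
cleanly: 5e3 cells/ml stays at ~99.7% of air saturation, 5e4 at ~97%, and
5e5 falls to ~74% - the ordering, not the exact curve, is the reproducible
claim, since the measured curves come from undeposited probe data.

# Image analysis

Bubbles image as dark-rimmed circles in transmitted light. The original
study's segmentation software is undescribed, so the detector here is a
deliberately standard pipeline: background subtraction (pixelwise median of
the first three frames, taken before bubbles appear), normalisation, Sobel
gradient magnitude, Otsu threshold on the gradient (never below a robust
noise ceiling, median + 5 MAD, which protects frames containing one faint
object from Otsu's tendency to cut into the noise), hole filling, a one-
pixel erosion (compensating the outward spread of the centred gradient),
connected components, a circularity filter (4*pi*A/P^2 with the perimeter
measured on the traced contour, default threshold 0.7 - merged bubble pairs
fall below it and are kept but flagged), and an equivalent-area-disk
radius. Tracking is greedy nearest-centroid linking (default gate 10 px)
with ties broken by distance then track id; unmatched detections open new
tracks (nucleation), unmatched tracks terminate (dissolution).

Benchmark protocol: because the renderer draws bubbles from 1 px while the
detector's floor is 2 px, a bubble crossing the floor is ambiguous in the
crossing frames for *any* seed. Recovery is therefore scored on bubbles at
least the floor plus the radius error budget (0.5 px noise-free, 1 px at
default noise) - zero misses and zero false positives are required there,
with radius RMS error within the budget.

# Growth-curve statistics

Each bubble's radial trajectory is fitted with the one-phase association
model `R(t) = R_plateau * (1 - exp(-k (t - t0)))`, `t0` fixed at first
detection (the zero-offset form; whether the original fits estimated an
offset is unknown, and the zero-offset choice matches "growth from
nucleation"). The fit is robust: iteratively reweighted least squares with
Tukey bisquare weights (c = 4.685), scale from the MAD (an exact interim
fit - scale below 1e-10 - reverts to unit weights), at most 200 iterations,
relative parameter tolerance 1e-8; the inner weighted problem is solved by
Levenberg-Marquardt. Initialisation: plateau from the largest radius, rate
from the first crossing of half of it. The derived half-life is
`t_half = ln 2 / k` exactly. Trajectories shorter than 5 points or constant
are excluded from fitting but still count toward nucleation. Per-phantom
mean metrics are regressed on log10(density) by ordinary least squares
(densities span two decades; a linear axis is available), reporting R^2 and
the two-sided slope p; at least three phantoms are required - with two, any
line is exact.

# Synthetic data

The generators exist to exercise the pipeline with known truth, not to
imitate the study's bubble population: plateau radii lognormal (median
50 um, geometric sd 1.4), rates lognormal (median 0.02 /s, gsd 1.5),
births uniform over the first 100 s of decompression, optional dissolution,
multiplicative radius noise (default 5%), the study's imaging schedule
(100 x 1 s, 50 x 30 s, 12 x 5 min, final at 2 h; analyses here thin the
slow phase 2x). Stacks render each bubble as a dark annular rim with a
lighter lumen on a light background, Gaussian PSF, additive noise,
non-overlapping placement by rejection sampling. Every generator is a pure
function of (parameters, seed) and leaves the caller's RNG untouched. What
passing recovery tests do *not* show: robustness to uneven illumination,
optical distortion near large bubbles, overlapping growth, or focal drift -
real stacks have all of these.

# Viability arithmetic

Live fractions follow the counting formula
`100 * calcein / (calcein + ethidium)` on manually counted images, taken
as tabulated input. The geometric expected-death model multiplies a 2D
per-exposure death rate by the fraction of cells actually exposed in 3D:
50% bubble contact x 30% gives 15%, 20% hyperoxic exposure x 20% gives 4%.
Only group means and sds are reported; inferential statistics on the
study's own counts are out of scope because those counts are not deposited.

# Design choices that were genuinely open

* **Repository shape.** The package is organised as an analysis workflow -
  numbered drivers under `analysis/` over a fully tested package core -
  because the scientific result is a sequence of analyses, not a shell
  tool; the drivers plus `run_probe_pipeline()` / `run_dive_pipeline()`
  are the command surface, and no separate CLI binary is shipped.
* **"80 psi" is gauge.** Chamber regulators read gauge pressure, so the
  hold sits at 1 atm + 80 psi absolute; `pressure_is_gauge = FALSE`
  restores the other reading. Profiles live on a uniform 0.5 s grid with a
  13 psi/s hardware cap enforced at construction, and are linearly
  interpolated (whether the rig stepped or ramped between grid points is
  unknown).
* **Sham control.** The acellular sham dive (constant 1 atm, sigma = 0) is
  the configuration whose mid-plane tension map is exactly 1.0 atm
  everywhere; any cellular phantom consumes oxygen and sits slightly
  below.
* **Compiled core.** The ADE march is C++ (precomputed neighbour tables,
  whole-run marching) because a 3D finite-difference solver is exactly
  where R packages reach for compiled code; the per-step R-visible
  `ade_step()` is retained and tested to agree with the march bit for bit,
  and the FTCS reference stays in plain R so the two routes share no code.

# Problem sizes used in the bundled runs

Tests and the acceptance script use the 0.34 mm lattice (~16k voxels,
14400 steps for 8 h), 200 trajectories for fit-recovery statistics, and
132-frame 300 px stacks with 6-8 bubbles for segmentation scoring; the
full test suite and the acceptance script each complete in a few minutes
on one core. All of these sizes are package choices recorded here so the
reported numbers are reproducible at the stated scale.

# Known limitations

Bubbles do not feed back on the dissolved-gas field (no gas exchange with
the simulated tension map, no Rayleigh-Plesset growth model); temperature
dependence of solubility is ignored; the lateral cylinder boundary is
staircase-approximated; nucleation positions in the generator are uniform
rather than biased by the simulated gas gradient (the qualitative
observation that bubbles form preferentially near the high-tension upper
surface is reproduced by the transport model, not asserted by the
generator).
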