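---
title: "Planning irreversible electroporation in tumor-mimicking hydrogels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning irreversible electroporation in tumor-mimicking hydrogels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Irreversible electroporation (IRE) ablates tissue non-thermally: above a
tissue-specific electric-field threshold, high-voltage microsecond
pulses permanently permeabilize cell membranes and the exposed region
dies. Planning an IRE treatment therefore reduces to a field problem —
given needle-electrode positions and pulse amplitudes, which region of
tissue sees a field above the threshold? — plus an estimation problem:
what *is* the threshold for the tissue at hand?

`ireplan` implements both directions for cell-laden hydrogel phantoms
that mimic hepatocellular carcinoma (HCC) and for voxelized tumor
models. The forward direction solves the field and converts it into
ablated areas, volumes and tumor-coverage maps. The inverse direction
takes measured ablation areas (in the lab: segmented live/dead confocal
images; here: synthetic stand-ins) and returns the field threshold that
reproduces them, pooled into a mean ± SD estimate. For Hep-G2-laden
hydrogels this procedure yields an experimental threshold of
544 ± 61 V/cm, about two-thirds of the 800 V/cm reported in vivo for
healthy liver — both values are built in as the default classification
thresholds for coverage maps.

## The field model

Each pulse is quasi-static: at 100 µs pulse width the hydrogel behaves
as a resistive conductor, so the potential obeys the conduction equation

$$\nabla \cdot \big(\sigma(\lvert \mathbf{E} \rvert)\, \nabla \varphi\big) = 0,
\qquad \mathbf{E} = -\nabla \varphi,$$

with the energized needle at the pulse amplitude, the paired needle
grounded, and the plastic well wall insulating (zero normal flux).
Displacement currents, electrode-interface impedance, pulse-train
dynamics and Joule heating are all outside the model — temperatures in
the phantom experiments stay far from protein denaturation, and the
threshold abstraction absorbs pulse-number effects.

Electroporation itself raises membrane conductance, so the bulk
conductivity grows with the local field. The package models this with a
logistic transition

$$\sigma(E) = \sigma_0 + (\sigma_f - \sigma_0)\,
  \mathrm{logit}^{-1}\!\Big(\frac{E - E_c}{E_w}\Big),$$

with liver defaults $\sigma_0 = 0.4$ S/m, $\sigma_f = 1.6$ S/m. The
transition midpoint $E_c = 500$ V/cm and width $E_w = 100$ V/cm are
package choices (the cited sigmoid is not fully parameterized in the
source literature): they place the transition across the
reversible-to-irreversible range, and both are arguments of
`conductivity_model()`. Calibrated constant conductivities (e.g.
0.022–0.032 S/m for small Hep-G2 hydrogels, recovered from
inter-electrode resistance readouts by `calibrate_conductivity()`) are
the second supported form; for constant $\sigma$ the problem is linear
and the field shape is independent of $\sigma$.

### Discretization and the nonlinear solve

The solver uses a regular Cartesian cell-centered grid (default
0.01 cm for wells, the tumor voxel size for 3D) with an embedded
boundary: a cell belongs to the domain iff its center does. Fluxes use
harmonic-mean face conductivities, giving a symmetric positive-definite
5-/7-point system solved by a supernodal sparse Cholesky factorization
(CHOLMOD via the Matrix package). Internally everything stays in the
bench units of the application (cm, V, V/cm, S/m) — the grid spacing
cancels from the 2D face weights, and only the current integration
converts the modeled 3 mm electrode height to meters.

Field-dependent conductivity is resolved by Picard iteration with
under-relaxation 0.5: solve at the current $\sigma$ field, re-evaluate
$\sigma(\lvert E\rvert)$, repeat until the relative max-norm change of
$\lvert E\rvert$ drops below $10^{-3}$ (at most 50 iterations; the
24-well case converges in about 6). The field magnitude uses central
differences, one-sided at boundaries. Needles not part of the active
pair are removed from the conductive domain (insulating holes): how the
original experiments treated floating metal during other pairs'
activations is not documented, and the insulating choice is the
simplest that keeps each activation a two-electrode problem.

Wells are solved as 2D axial cross-sections, because ablation in the
phantoms is validated as an area in confocal planes; the same solver
runs on 3D voxel grids for tumor domains. Verification rests on the
coaxial benchmark — a centered needle with a grounded wall has the
closed form $\varphi(r) = V \ln(R/r)/\ln(R/a)$ and resistance
$\ln(R/a)/(2\pi\sigma h)$ — compared using the equal-area effective
radii of the discrete electrode and wall cell sets, which isolates
solver error from the $O(h)$ staircase representation of circles on a
Cartesian grid. At the default spacing the potential agrees within 3%
of the applied voltage, interior fields and the resistance within 2%,
and the error decreases under refinement (see `test-solver.R`).

## Plans, superposition and ablation measures

Multi-needle treatments energize one pair at a time.
`run_plan()` solves each activation independently and combines them as
the *pointwise maximum* of the field magnitude. Activations are
sequential in time, so each location's electroporation state is
governed by the strongest exposure it ever receives; summing fields
from different instants (vectorially or in magnitude) would manufacture
exposure that never physically co-occurred. This reading of "cumulative
field" is a package decision — the alternatives are rejected in the
code, not just undocumented.

`ablation_sweep()` converts a cumulative field into the monotone map
threshold → ablated measure by counting grid cells at or above each
threshold (boundary cells count as ablated; cell-center counting, no
sub-cell correction — the refinement test bounds the induced error at
under 2% for the default well). Sweep granularity mirrors bench
practice: 1 V/cm over 200–1200 V/cm for small wells, 20 V/cm up to
1600/2500 V/cm for larger ones. `coverage_fraction()` normalizes by the
region measure, and `classify_field_map()` produces the tri-level
untreated / above-experimental / above-reported map at 544 and
800 V/cm.

## Threshold inversion

`invert_threshold()` inverts the sweep by monotone piecewise-linear
interpolation; exact (up to float round-trip) table ties return the
smallest threshold. Measured areas larger than anything the model can
produce raise an explicit out-of-range error rather than clamping — a
silent clamp would bias pooled estimates. Areas below the sweep minimum
return the upper sweep bound flagged `boundary = TRUE`.
`aggregate_thresholds()` pools a flat vector of per-sample thresholds
into mean ± sample SD (n−1 denominator); any grouping by protocol or
replicate is the caller's concern.

`threshold_recovery_experiment()` closes the loop: deliver a plan,
draw noisy synthetic areas at a known true threshold, invert, pool.
With zero noise every sample recovers the truth within one sweep step;
at 5% area noise and n = 9 the mean lands well inside the ±61 V/cm
experimental spread (the acceptance script reruns exactly this).

## What the synthetic data emulate — and what they do not

The wet-lab pipeline this package replaces measured ablation on
confocal z-stacks, read resistances off the pulse generator, and took
tumor shapes from CT segmentations of three patients. The synthetic
module generates each stand-in as a pure function of its parameters and
a seed:

* `synth_ablation_measurements()` — replicate ablation areas as the
  forward model's area at the true threshold times $(1 + \varepsilon)$,
  $\varepsilon \sim \mathcal{N}(0, \mathrm{CV}^2)$, clipped to the
  physical range. Multiplicative noise was chosen because replicate
  scatter in bench data grows with ablation size. The default CV of
  0.05 is a package choice of realistic replicate variability, not a
  measured value.
* `synth_tumor()` — star-convex bumpy spheres
  $r(\theta,\phi) = R(1 + b\,p(\theta,\phi))$ with seeded low-order
  angular harmonics, voxelized at 0.5 mm; $R = 5.2$ mm reproduces the
  0.6 cm³ small-tumor mold volume.
* `synth_resistance()` — the forward resistance of a known-conductivity
  phantom with multiplicative noise; `calibrate_conductivity()` is its
  exact inverse at zero noise.
* `render_ablation_stack()` / `measure_stack()` — binary live/dead
  z-stacks (default 5 slices over the 2 mm scanned thickness)
  rasterized from the field, and their pixel-counting measurement,
  mutually consistent with the sweep to rasterization tolerance.

What passing tests on these generators shows is *estimator*
correctness: the inversion recovers a threshold that really generated
the data, with the right noise response. It does not validate the
biological threshold itself, staining/segmentation error, hydrogel
inhomogeneity, or electrode-tissue contact effects — none of which the
generators model.

## Problem sizes and runtimes

Defaults were chosen so a full planning run is interactive on one CPU:
the 24-well grid at 0.01 cm is ≈156², one constant-σ solve well under a
second and a field-dependent solve a few seconds; the six-pair 6-well
plan at 0.02 cm runs in seconds; the 0.5 mm small-tumor domain is 43³
(≈80k unknowns) and a six-activation plan takes ≈20 s. The test suite
uses 0.02–0.04 cm grids wherever the property under test is
grid-agnostic, and 0.005 cm only for the refinement checks.

## Configuration and reports

Run configurations are YAML with unit-suffixed keys (`spacing_cm`,
`amplitude_V`, `E_min_V_per_cm`, ...); YAML was picked because it is the
structured-text format with a mature parser in the R dependency stack.
`cmd_plan()`, `cmd_invert()` and `cmd_simulate()` (and the `exec/ireplan`
script wrapping them) write their results only to files — CSV tables,
8-bit TIFF label maps, legacy-VTK field grids, JSON summaries — plus a
manifest with the full config, its hash and the seed, so any report can
be reproduced exactly. Progress goes to stderr.

## Known limitations

* The staircase domain boundary limits pointwise field accuracy near
  electrodes to a few percent at default spacing; quantities integrated
  over the domain (areas, coverage, resistance) are better behaved.
* No thermal model: protocols that would heat real tissue are not
  flagged.
* The pulse count enters only through treatment time and metadata; the
  experimentally observed dependence of ablation on pulse number is not
  part of the field model.
* Inactive-needle handling (insulating holes) is an assumption; a
  floating-conductor boundary condition would bracket the truth from
  the other side and is not implemented.
* The co-culture annulus assigns each region one conductivity; no
  interface layer between the tumor core and the endothelial ring.

```{r example}
library(ireplan)

g <- make_well_geometry(24, grid_spacing = 0.01,
                        conductivity = conductivity_model(0.027))
e <- place_electrodes(g, "pair", 0.8)
plan <- activation_plan(c("E1", "E2"), pulse_protocol(1100, 100))

est <- threshold_recovery_experiment(g, e, plan, true_threshold = 544,
                                     noise_cv = 0.05, n_samples = 9,
                                     seed = 42)
est
```
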