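---
title: "Methods: geometry-based simulation of panretinal photocoagulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry-based simulation of panretinal photocoagulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prpsim)
```

## The model

Panretinal photocoagulation (PRP) scatters hundreds of 400-um laser burns
across the peripheral retina. Every burn destroys the photoreceptors under
it, and because rod density varies strongly with eccentricity, two
treatment patterns with the same *photocoagulated area* can destroy very
different *numbers of photoreceptors*. This package quantifies that
difference with two metrics:

* **photocoagulation index** — photocoagulated lesion area / whole retinal
  area, in percent (purely geometric);
* **photoreceptor destruction index** — photoreceptors destroyed / total
  photoreceptors, in percent (density-weighted).

The simulation rests on three constructions.

**1. Equal-area flattening.** A retinal region is treated as a spherical
dome with base radius $c$ and height $h$; its curved surface area is
$S = 2\pi r h = \pi(c^2 + h^2)$, so the region maps to a flat circle of
radius $\sqrt{c^2+h^2}$ with *exactly* the same area. Applied to a
standard adult eye this gives the three concentric radii used throughout,
stored in `equivalent_disc()`:

| region | equivalent radius |
|---|---|
| whole retina (ora serrata) | 18.6 mm |
| retina up to the equator | 15.6 mm |
| central PRP-free zone | 5.14 mm |

These radii are treated as authoritative named constants (the underlying
$c,h$ dimensions come from anatomy textbooks and are not re-derived);
users can override any of them. All downstream geometry happens on the
flattened disc — no spherical coordinates are used anywhere else.

**2. The island-shaped solid.** The rotationally averaged rod density
$\rho(e)$ (cells/mm$^2$) against eccentricity $e$ (mm on the flattened
disc), rotated about the vertical axis, forms an island-shaped solid of
revolution. With the density axis scaled so that 1 mm of height
corresponds to $10^4$ cells/mm$^2$, 1 mm$^3$ of solid volume corresponds
to exactly $10^4$ photoreceptors; `count_from_volume()` /
`volume_from_count()` implement this exact bookkeeping. The total count
is

$$N = 2\pi \int_0^{R}\rho(e)\,e\,de \;-\; \pi r_d^2\,\rho(e_d),$$

the second term removing the photoreceptor-free optic-disc cylinder
(default radius 0.75 mm at eccentricity 3.4 mm — standard anatomy; the
hollow's dimensions are configurable and calibration absorbs the choice).

**3. Punch-out integration.** Each burn is a closed disc punched at right
angles through the solid, so the destroyed count per spot is the area
integral $\iint_{spot}\rho(|p|)\,dA$, and — since generated layouts never
overlap — a layout's total destruction is the plain sum over spots.
Layouts that do overlap are rejected rather than union-integrated.

## Spot layouts

`generate_annulus_layout()` packs spots deterministically on concentric
rings inside a closed annulus:

* center pitch along a ring = `spot_diameter + spacing`
  (0.4 mm + 0.4 mm by default: "one spot width apart");
* first ring tangent to the inner boundary; ring separation
  `(d+s)·√3/2` in `hex` mode (default) or `d+s` in `square` mode;
* each ring holds `floor(2π·radius / pitch)` evenly spaced spots, with a
  half-pitch angular offset alternating between rings to avoid radial
  alignment artifacts;
* a spot is kept iff its closed disc lies inside the closed annulus —
  tangency is allowed, crossing the border is not.

The exact CAD arrangement behind the published 1261 (scatter) and 1837
(full-scatter) spot counts is not derivable from the stated rules; hex
packing lands a few percent short. The `count_match` mode therefore
scales only the circumferential pitch (found by bisection) until the
count matches a requested target exactly — scaling the radial pitch as
well would add whole rings of ~100 spots at a time and overshoot. These
replication layouts keep both layout invariants (non-overlap,
containment), which are validated exhaustively on every construction.

`generate_single_ring()` places one ring of burns at a given radius; at
4.94 mm — tangent just inside the PRP-free zone — with the default 0.8 mm
pitch it holds `floor(2π·4.94/0.8)` = 38 spots (published value: 39; the
printed count presumably rounds up, and the ring radius used there is
unstated).

## The synthetic density profile

The measured rod topography behind the published figures is not tabulated
anywhere in accessible form, so the package ships a *synthetic* profile
(`packaged_fixture()`, CSV copy in
`inst/extdata/synthetic_calibrated_profile.csv`) built by
`parametric_profile()`:

$$\rho(e) = A_c\, e^{-e^2/2w_c^2} \;+\;
  A_r\, e^{-(e-e_r)^2/2w_r^2}\, e^{-\max(0,\,e-e_r)/L}.$$

The first term is a narrow central peak, the second a broad rod "ridge"
at $e_r = 4$ mm whose peripheral side decays exponentially. The decay is
applied only peripheral to the ridge: a decay acting at all
eccentricities would shift the density maximum away from $e_r$, breaking
the constructed-peak property the generator promises.

Defaults (amplitudes $A_c = 10^4$, $A_r = 1.5\times10^5$ cells/mm$^2$;
widths $w_c = 0.5$, $w_r = 15$ mm; decay length $L = 12$ mm) were chosen
once so that, after calibrating the total to the published 96,571,900
cells, the count-matched scatter and full-scatter destruction indexes
land near the published 16.2% / 19.8%, and then frozen. The tuning is
fully deterministic and reproducible; it is a *calibration to published
totals*, not a fit to measured topography. Consequences to keep in mind:

* the fixture is anatomically plausible in broad strokes (ridge density
  ≈ 1.9×10$^5$, periphery ≈ 6×10$^4$ cells/mm$^2$, scatter-annulus mean
  ≈ 10$^5$) but carries unrealistically many "rods" at the fovea — a
  region PRP never touches, so no simulated quantity depends on it;
* only rods are modelled (cones are 10–60× sparser in the treated area
  and are not counted);
* the profile is rotationally symmetric by construction; real rod maps
  deviate by ≲15% between meridians. `perturbed_profile()` adds
  seeded multiplicative lognormal node noise (unit mean, relative SD
  `noise_sd_fraction`) to probe this: because the destruction index is a
  ratio of two integrals over the same profile, node noise largely
  cancels (the test suite measures a coefficient of variation far below
  the injected noise level).

Passing tests on this fixture therefore demonstrate that the *machinery*
(flattening, integration, layout generation, index arithmetic) reproduces
the published results given a density curve with the right gross shape —
not that the fixture equals the measured topography. Exact reproduction
of the published destroyed counts would require the original tabulated
curve; the acceptance checks carry a ±2-percentage-point band for this
reason.

## Numerical choices

* **Total count**: the radial integrand $\rho(e)e$ is piecewise
  quadratic on the grid, integrated in closed form — exact, no quadrature
  error. Density is interpolated linearly between nodes and is zero
  beyond the last node.
* **Per-spot integral**: midpoint rule on a Cartesian grid of pitch
  10 um clipped to the spot disc, normalized by the exact disc area
  (i.e. $\pi r^2$ × mean density over retained grid centers). The
  normalization makes the rule exact for constant density and cancels
  the lattice boundary-area error; halving the step changes fixture spot
  counts by well under 0.1%, and the estimate sits within 3 standard
  errors of the seeded Monte-Carlo rejection-sampling oracle
  (`mc_count_in_spot()`) on ≥95% of random spots.
* **Grid defaults**: profile step 0.1 mm to the whole-retina radius
  18.6 mm (187 nodes) — fine enough that quadrature error is invisible
  at reporting precision; quadrature step 0.01 mm.
* **Reporting precision**: counts are computed at full double precision
  and rounded to the nearest 100 only in rendered reports (consistent
  with 2-decimal mm$^3$ volumes × 10$^4$); indexes are rendered to one
  decimal. JSON outputs keep full precision.
* **Determinism**: layout generation contains no randomness; the Monte
  Carlo oracle and noise generator take explicit seeds and restore the
  caller's RNG state.

## Open design points, resolved

* The published areal photocoagulation indexes (14.3% / 21.3%) differ
  slightly from $100\,n(d/2)^2/R^2$ evaluated with the published spot
  counts (14.58% / 21.24%). The package computes the closed form from
  the layout; the discrepancy (≲2% relative, source presumably the
  original CAD area measurement) is documented, not resolved.
* Whether the optic-disc cylinder was hollowed before or after scaling
  the solid is unstated; the package hollows first and calibrates after,
  which makes the choice immaterial to every reported index.
* The arcade-row scenario uses ring radius 4.94 mm (spot tangent inside
  the 5.14 mm free-zone boundary), the natural reading of "one
  additional row inside the vascular arcade".

## Problem sizes

The shipped tests and the acceptance script run the full-scale problem:
187-node profiles, layouts up to 1837 spots, 10-um quadrature, a
100-case random invariant sweep at 20-um quadrature, and Monte-Carlo
cross-checks at 4000 samples per spot. A full scatter + full-scatter
simulation pair completes in roughly a second on one core.

## Worked example

```{r example}
disc <- equivalent_disc()
profile <- packaged_fixture()

scatter <- generate_annulus_layout(layout_config(
  inner_radius = disc$radius_free, outer_radius = disc$radius_equator,
  radial_pitch_mode = "count_match", target_count = 1261))
full <- generate_annulus_layout(layout_config(
  inner_radius = disc$radius_free, outer_radius = disc$radius_total,
  radial_pitch_mode = "count_match", target_count = 1837))

res_s <- run_simulation(profile, scatter, disc)
res_f <- run_simulation(profile, full, disc)
res_s
render_summary_table(list(scatter = res_s, full_scatter = res_f))
```
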