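# prpsim

Geometry-based 3D simulation of panretinal photocoagulation (PRP) for
computational ophthalmology: how many photoreceptors does a given laser
treatment pattern actually destroy?

PRP treats severe retinal ischemia (proliferative diabetic retinopathy,
ischemic vein occlusion) by scattering hundreds of 400-um burns across the
peripheral retina. The classic **photocoagulation index** — lesion area /
retinal area — ignores that rod density varies several-fold with
eccentricity. This package weights every burn by the local photoreceptor
density and reports the **photoreceptor destruction index**, the fraction
of all photoreceptors destroyed. It is aimed at researchers comparing
treatment patterns (scatter vs full-scatter vs additional rows) in a
standardized geometric model.

## Model

* Each retinal region is a spherical dome with base radius *c* and height
  *h*; its curved area *S* = 2πrh = π(c² + h²) equals the area of a flat
  circle of radius √(c² + h²). The whole retina, the equator, and the
  central PRP-free zone flatten to concentric circles of radius 18.6,
  15.6, and 5.14 mm — all geometry lives on this equal-area disc.
* The rotationally averaged rod density ρ(e) (cells/mm²) rotated about
  the vertical axis forms an island-shaped solid whose volume encodes the
  photoreceptor count exactly: 1 mm³ ↔ 10⁴ cells (optic-disc cylinder
  hollowed out).
* Burns are closed discs punched at right angles through the solid:
  destroyed count per spot = ∬ ρ(|p|) dA over the spot, summed over a
  deterministic, non-overlapping annular layout.
* destruction index = 100 · destroyed / total;
  photocoagulation index = 100 · n·(d/2)² / R².

Because the measured rod topography behind the published model is not
tabulated, the package ships a parametric synthetic profile calibrated so
the total is exactly 96,571,900 cells (9657.19 mm³); see the methods
vignette (`vignettes/prp-simulation.Rmd`) for what that does and does not
validate.

## Worked example

```r
library(prpsim)
disc <- equivalent_disc()        # 18.6 / 15.6 / 5.14 mm regions
profile <- packaged_fixture()    # calibrated synthetic rod density

scatter <- generate_annulus_layout(layout_config(
  inner_radius = disc$radius_free, outer_radius = disc$radius_equator,
  radial_pitch_mode = "count_match", target_count = 1261))
res_s <- run_simulation(profile, scatter, disc)
res_s
#> PRP simulation result
#>   spots                         1261
#>   total photoreceptors          96,571,900
#>   destroyed photoreceptors      15,826,200
#>   residual photoreceptors       80,745,700
#>   destruction index             16.4 %
#>   photocoagulation index        14.6 %
#>   residual solid volume         8074.57 mm^3
```

The 1261-spot scatter pattern destroys 15.8 million of 96.6 million
photoreceptors: a destruction index of 16.4% against an areal
photocoagulation index of 14.6% — the excess reflects that the treated
annulus is denser than the retinal average. Running the full-scatter
pattern (`outer_radius = disc$radius_total`, `target_count = 1837`) the
same way and tabulating both:

```r
render_summary_table(list(scatter = res_s, full_scatter = res_f))
#>                              quantity    scatter full_scatter
#> 1             residual_photoreceptors 80745700.0   77280800.0
#> 2            destroyed_photoreceptors 15826200.0   19291100.0
#> 3 photoreceptor_destruction_index_pct       16.4         20.0
#> 4          photocoagulation_index_pct       14.6         21.2
#> 5                             n_spots     1261.0       1837.0
```

Extending scatter to full-scatter adds 3.6 percentage points of
destruction — scatter PRP already destroys about 4/5 of what full-scatter
does.

A thin command-line wrapper is installed at
`system.file("cli", "prpsim", package = "prpsim")` with subcommands
`simulate`, `layout`, `synth`, `calibrate`, `compare`.

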