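# strainavoid

Finite-element modelling of **oblique cardiac cell alignment** in grooved
elastomer stretch chambers, plus the image- and video-based quantification
that goes with such cultures.

## The scientific problem

Myocytes in the heart wall are arranged helicoidally: their orientation
rotates through the wall thickness, and this off-axis layout underlies the
heart's twisting ejection motion. In vitro, two strong alignment cues are
available:

* **cyclic uniaxial stretch** orients cells *perpendicular* to the stretch
  axis (strain avoidance: stress fibers disassemble along directions that
  are cyclically compressed during the release half-cycle);
* **microgroove topography** orients cells *along* the grooves, because
  cellular traction condenses the cell-laden hydrogel against the groove
  walls and the groove axis is the least-compressed direction.

When a 3D hydrogel culture in 350 µm grooves is stretched *along* the
groove direction, the cues conflict and cells settle at an oblique angle —
a possible route to engineering helicoidal cardiac tissue. This package
implements a lumped mechanical model of that competition for engineers and
mechanobiologists designing such stretch-chamber experiments.

## The model

Each cue is a static linear-elasticity solve on a hexahedral mesh of the
chamber (or a periodic one-groove unit cell):

* applied stretch at peak amplitude (prescribed end displacement);
* cellular self-condensation as a stress-free contraction eigenstrain over
  the cell-bearing region, with an elastic-spring sidewall condition
  representing the hydrogel's partial detachment from the groove walls.

For a unit direction *u*, the directional stress-fiber elongation is
*e(u) = 1 + uᵀεu* (values < 1 are compression). The cyclic cue uses the
**negated** peak strain (the compressive release phase); the static cue
uses the condensation strain directly. The two combine through the
nonlinear strain-avoidance addition law

    e_tot = (e_cyclic⁻ⁿ + e_self⁻ⁿ)^(−1/n),   n = 4,

which weights compression more heavily than extension. The predicted
orientation is the in-plane direction maximising *e_tot*, reported in
degrees from the stretch axis and folded to [0°, 90°].

## Worked example

```r
library(strainavoid)

# 3D hydrogel in grooves, 15% cyclic stretch along the groove axis
res <- run_scenario("3d_parallel")
res
#> Scenario: 3d_parallel
#>   applied stretch 15% -> effective axial strain 15.0%
#> Strain-avoidance orientation prediction [3d_parallel]
#>   preferred angle: 51.0 deg from the stretch axis
#>   combined elongation range: [0.7653, 0.7941] (n = 4)
```

The cyclic cue alone would give 90° and the groove-condensation cue alone
0°; with the calibrated contraction (peak in-plane self-compression equal
to the 0.15 stretch amplitude) the combined prediction is an oblique 51°.
The same call with `"2d_parallel"`, `"2d_perpendicular"` or
`"3d_perpendicular"` returns 90° — on stiff elastomer the stretch cue
dominates completely, and with stretch across the grooves both cues agree.
`plot(res$prediction$profile)` draws the polar elongation profiles.

Strain transmission across the nine seeding-by-topography cases at 36%
applied stretch (`strain_transmission()`) shows the stress concentration
of grooves running across the stretch axis, e.g. for the 3D hydrogel case:

```r
strain_transmission()[9, ]
#>       seeding    topography applied_pct effective_pct    ratio
#> 9 hydrogel_3d perpendicular          36      59.50091 1.652803
```

i.e. the gel in a transverse groove feels ~1.65× the applied strain.

Synthetic quantification round-trips:

```r
img <- generate_cell_image(synthetic_image_spec(mean_angle = 30,
                                                concentration = 8, seed = 1))
quantify_orientation(img)
#> Axial orientation distribution
#>   mean angle: 30.7 deg (axis 30.7 deg), order parameter 0.873

v <- generate_beating_video(beating_video_spec(base_frequency = 120,
                                               noise_level = 0.1,
                                               phase_gradient = 1, seed = 1))
phase_map(v)
#> Block-wise beating maps (4x4 blocks, 16 valid)
#>   median frequency: 2 Hz (120 bpm)
#>   phase range: [-24.1, 24.1] deg
```

The orientation analysis recovers the specified 30° mean within a degree;
the beating analysis recovers the 120 bpm rate exactly and the linear
phase lag across the field.

Batch runs go through `run_report(run_config(...))`, which writes
per-scenario profiles (CSV), orientation summaries (JSON), optional VTK
fields and polar plots, a consolidated angle table, and a provenance log;
identical configurations produce byte-identical reports. A thin
command-line wrapper is included at `inst/scripts/run_scenarios.R`.

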