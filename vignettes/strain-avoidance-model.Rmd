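---
title: "Modelling oblique cardiac cell alignment by nonlinear strain avoidance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling oblique cardiac cell alignment by nonlinear strain avoidance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cardiomyocytes in the ventricular wall are locally parallel but globally
arranged in a helix: the fiber angle rotates through the wall thickness,
and this oblique, off-axis organisation is essential to the heart's
wringing ejection motion. In vitro, two robust alignment cues are
available to engineer cell orientation: cyclic uniaxial stretch, which
orients cells *perpendicular* to the stretch axis, and microgroove
topography, which orients cells *along* the grooves. When a cell-laden
hydrogel is cultured in grooves and stretched along the groove direction,
the two cues conflict, and cells settle at an intermediate, oblique angle
— a candidate mechanism for engineering helicoidal tissue.

`strainavoid` implements a lumped mechanical model of this competition,
together with the image- and video-based quantification used to
characterise such cultures.

## The model

Both cues are reduced to static linear-elasticity solves on a mesh of the
culture chamber (or of a periodic one-groove unit cell):

* **Cyclic stretch** is represented by its peak-amplitude strain field
  $\varepsilon^{\mathrm{stretch}}$ (quasi-static assumption: 1 Hz is far
  below any structural resonance of the chamber, so only the amplitude of
  the cycle matters). The cue acting on the cells is the *compressive
  release phase* of the cycle, i.e. the negated peak field.
* **Self-condensation** — the contraction of the cell-laden hydrogel (or
  cell layer) by cellular traction — is encoded as a stress-free
  contraction eigenstrain $-c\,\mathbf{I}$ over the cell-bearing region
  (in-plane biaxial, $-c(\mathbf{I} - \hat z \hat z)$, for a 2D layer,
  which contracts isometrically only within the substrate plane).

For a unit direction $u$, the directional elongation of a stress fiber is
the linearised stretch ratio

$$e(u) = 1 + u^\top \varepsilon\, u ,$$

so $e<1$ is compression and $e>1$ extension. The two cues combine through
the nonlinear addition law

$$e_{\mathrm{tot}} = \left( e_{\mathrm{cyclic}}^{-n} +
  e_{\mathrm{self}}^{-n} \right)^{-1/n}, \qquad n = 4 ,$$

whose negative powers weight compression more than extension — the
essence of *strain avoidance*. The law is symmetric, homogeneous
(`combine(ka, kb) = k combine(a, b)`), bounded by $\min(e_a, e_b)$, and
tends to the minimum as $n \to \infty$. The predicted orientation is the
direction maximising $e_{\mathrm{tot}}$ (least effective compression),
searched on a grid over the substrate plane and folded to $[0^\circ,
90^\circ]$ from the stretch axis (orientations are axial data).

```{r law}
library(strainavoid)
combine_elongations(0.85, 1.0775, n = 4)  # competing cues
```

## Geometry, mesh and solver

The chamber family is parametric: a 20 x 10 x 10 mm elastomer trough with
a 2 mm culture membrane, 0.1/5 mm sidewalls, and square 350 x 350 um
grooves spaced 350 um apart, carved into the membrane surface (the
membrane is locally thinner under each groove, which is what concentrates
strain when stretch runs across the grooves). Two domains are supported:
the full coarse chamber, used to verify strain transmission from the
clamped ends to the membrane centre, and a periodic one-groove unit cell,
on which all orientation predictions run — the orientation rule only
needs the groove-local strain state, and the unit cell resolves it at
desk-scale cost.

Meshes are graded tensor grids of trilinear hexahedra with grid lines on
every material boundary, so interfaces are conforming, region/boundary
tags are exact, and the meshed volume equals the parametric solid volume
identically. Axis-aligned boxes are affine elements: the solver passes
the uniform-strain patch test to machine precision, which anchors the
verification suite. With groove refinement on, elements inside grooves
are at most 0.1 mm across.

Unit-cell boundary conditions (all exposed through `default_bcs()`):

* stretch: symmetric end displacements $u_x = \pm \varepsilon L/2$ on the
  cut faces; mirror plane $u_y = 0$ on one side face; the opposite face is
  a *tied* plane — it stays planar with a single unknown offset carrying
  zero net traction. This relaxed-periodic condition lets the membrane
  develop its global transverse Poisson contraction, which a rigid
  $u_y=0$ pair would suppress and which materially affects the
  transverse leg of the cyclic cue.
* condensation: $u_x = 0$ mirror planes on the cut faces (the groove and
  membrane continue periodically; the chamber ends fix the total length),
  the same tied transverse face, membrane underside held flat.

For 3D hydrogel in grooves, extended culture partially detaches the gel
from the groove sidewalls. The condensation solve therefore runs on the
hydrogel subdomain with the groove floor bonded and a distributed elastic
spring (Robin condition, stiffness in Pa/m) on the sidewall facets; the
elastomer wall, ~47x stiffer than the gel, is treated as rigid support
for this load. The spring spans the full range from fully detached
($k = 0$) to bonded ($k \to \infty$), and both limits are verified
against directly constrained solves.

## Calibrated parameters

Two quantities are not measurable directly and are set by stated rules,
not by hand:

* **Sidewall spring stiffness** (default rule: 50% fraction): $k$ is
  chosen so the groove-transverse contraction at the probe reaches half
  of its fully detached value — a neutral midpoint of the detachment
  range, since only "partial detachment" is known qualitatively. With
  default geometry and materials this gives $k \approx 1\times 10^8$
  Pa/m.
* **Cellular contraction magnitude**: in the soft 3D gel, cellular
  contraction and applied stretch produce local strains of similar
  magnitude; the eigenstrain $c$ is scaled (one linear solve) so the peak
  in-plane self-compression $|1 - e_{\mathrm{self}}|$ at the probe equals
  the 0.15 stretch amplitude. The peak is taken in-plane because the
  direction search is in-plane. Crucially, $c$ is a *cell* property: it
  is calibrated once on the 3D parallel-groove unit cell and reused for
  the 2D scenarios, where the same traction barely deforms the far
  stiffer elastomer — which is exactly why applied stretch dominates 2D
  cultures.

Remaining defaults: materials (cells 30 kPa / $\nu$ 0.49, gel 21 kPa /
0.2, elastomer 0.98 MPa / 0.49; near-incompressible constituents are
computed at 0.49, which trilinear hexahedra tolerate at these mesh
sizes without a mixed formulation), 2D film thickness 10 um (a typical
monolayer height), unit-cell length 1.4 mm (edge effects decay over a
groove width; the probe sits at the centre), angle grid 0.5 degrees.

```{r scenario}
res <- run_scenario("3d_parallel")   # ~15% stretch along the grooves
res$prediction$angle                 # oblique angle, degrees from stretch
plot(res$prediction$profile)         # polar view of the two cues
```

The probe is the representative location: groove midline at the unit-cell
centre, at groove half-height (3D), film mid-thickness (2D), or just
below the groove floor (unseeded). A probed angle rather than a
volume-averaged one is the default because the reported quantities are
point measurements of the groove interior; probe offsets are exposed.

## What the model predicts

With defaults, the four grooved scenarios give: stretch along grooves,
3D: an oblique angle (51 degrees on the converged unit-cell mesh — the
angle is insensitive to refinement from 0.35 mm down to 0.15 mm ambient
resolution); 2D on elastomer: 90 degrees for both groove orientations
(stretch dominance; the film's self-cue anisotropy on stiff elastomer is
of order $10^{-4}$ and cannot move the argmax); 3D with stretch across
the grooves: 90 degrees (both cues agree). A sweep of the contraction
magnitude moves the 3D parallel angle monotonically from 90 degrees
(stretch-dominated) toward 0 (groove-dominated); the plateau at exactly
90 for weak contraction is a real feature of the addition law — an
interior maximum only appears once the competing cue passes a finite
threshold.

## Synthetic quantification data

The two analysis modules ship with generators that emulate just the
features their estimators consume; passing recovery tests therefore
demonstrates estimator correctness, not robustness to everything real
microscopy produces.

* **Cell images**: elongated capsules with axial angles drawn from a von
  Mises distribution on doubled angles (concentration $\kappa$, 0 =
  isotropic), plus Gaussian noise. Not emulated: uneven illumination,
  cell crowding/overlap texture, out-of-focus light. Orientation is
  quantified by the structure tensor (gradient scale 2 px, tensor
  smoothing at twice that, coherence floor 0.2), reporting a normalised
  axial histogram, the circular mean of doubled angles folded to
  $[0^\circ, 90^\circ]$, and the resultant-length order parameter; a
  constant image reports "no orientation" rather than an angle. Marker
  expression is the thresholded area fraction (Otsu when no threshold is
  given, since none is prescribed).
* **Beating videos**: block-wise sinusoid or narrow-pulse trains at a set
  rate with a linear spatial phase lag and noise. Not emulated: motion
  artefacts, drift, irregular rhythms. Analysis is temporal peak
  detection (prominence >= 0.2 of the trace amplitude, spacing >= 0.25 s)
  on 16 px block means; local frequency is the reciprocal *median*
  inter-peak interval (median over mean for outlier robustness); phase is
  the circular mean offset of a block's beats from the reference-trace
  beats (global mean trace by default), in degrees of cycle. Peak times
  are refined to sub-frame precision by a parabolic fit, which removes
  frame-quantisation jitter from the phase maps. A block is valid only if
  its peaks are regular and the trace autocorrelates at the beat period —
  the autocorrelation gate is what rejects noise-only blocks whose
  spurious peaks the spacing rule alone would quasi-regularise.

## Numerical choices and degenerate inputs

* Ties in the direction search are broken toward the smaller angle, and
  profiles that are flat to within $10^{-12}$ relative report a
  no-preferred-direction flag instead of an arbitrary angle (isotropic
  contraction of a free block is the canonical case).
* The linearised elongation $1 + u^\top\varepsilon u$ is used rather than
  the finite-strain $\sqrt{u^\top C u}$, consistent with the all-linear
  material model; at 15% strain the two differ by under 1% (verified by
  test).
* Spring stiffness is exposed in Pa/m and converted to the internal
  mm/Pa unit system; solves use a sparse Cholesky factorisation of the
  reduced symmetric system.
* The applied stretch is specified as a strain (15% for orientation
  scenarios, 36% for the transmission campaign) and converted to an end
  displacement over the active gauge length; specifying the displacement
  directly is also supported.

## Known limitations

* Static linear elasticity only: no viscoelasticity, no contact — the
  sidewall detachment is lumped into the spring condition; no remodeling
  dynamics of the stress-fiber population, only the lumped orientation
  rule.
* The unit-cell predictions represent the chamber mid-region; clamp-end
  effects are visible only in the full-chamber solves.
* The 2D predictions sit at exactly 90 degrees: the model's stretch
  dominance on stiff elastomer is total, so the few degrees of off-axis
  tilt seen in 2D cultures are not resolved by this cue pair.
* Strain-concentration factors for grooves perpendicular to stretch are
  geometry-sensitive; the unit cell reproduces the amplification
  qualitatively (factor ~1.7 at the gel probe) but not any particular
  full-device value.

## Problem sizes

All shipped analyses are desk-scale by design: unit cells of ~900
elements (~4000 unknowns) solve in well under a second; the coarse full
chamber uses ~1400 elements; calibration adds ~15 small subdomain solves.
The synthetic image suite uses 256 px images and the beating suite
64 px x 300 frame stacks.
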