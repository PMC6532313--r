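---
title: "Analysing spinal curvature from torso surface scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing spinal curvature from torso surface scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinescan)
```

## The problem and the method

Scoliosis — a lateral spinal deviation of at least 10° in the frontal
plane combined with axial vertebral rotation — is conventionally monitored
with X-ray imaging (the Cobb angle). Optical 3D surface scans of the torso
offer a radiation-free complement: the spine leaves visible traces on the
back surface, and `spinescan` turns those traces into a quantitative
vertebral-column trajectory.

The pipeline works slice by slice:

1. **Transverse slicing.** The surface mesh (RAS frame: x toward the
   patient's right, y anterior, z superior; mm) is cut at 10–15 levels
   along the vertical axis. For triangle meshes the cut is the exact
   edge–plane intersection; raw point clouds use a thin slab (default
   half-width 2 mm) projected onto the plane. Each cut is ordered into a
   closed contour (angular sort around the centroid with a
   nearest-neighbour repair pass) and resampled to uniform arc length.

2. **Dip detection.** The tip of the spinous process shows as a
   characteristic dip — a local indentation toward anterior — on the
   posterior arc of the contour. The deepest indentation within the
   posterior 40% of arc length is taken, with sub-sample refinement by
   parabolic interpolation. Its *depth* is the prominence relative to the
   flanking posterior arch maxima; below 1 mm the slice reports no
   usable dip.

3. **Reflection axis.** The healthy body half is mirrored across a
   near-sagittal axis (angle, lateral offset) onto the pathological half.
   The clinical procedure places this axis by eye where the two halves
   agree; `fit_reflection_axis()` automates it as a *trimmed* least
   squares problem: minimise the mean squared distance from the reflected
   healthy points to the pathological half polyline, keeping only the
   best 70% of point distances (configurable), so regions deformed by a
   rib hump do not drag the axis. The optimiser is a multi-start grid
   (±10°, ±15 mm around the dip-vertical axis) followed by Nelder–Mead;
   solutions with |angle| ≥ 45° are rejected as non-sagittal.

4. **Offset correction for vertebral rotation.** Axial rotation of a
   vertebra skews the dorsal rib arches without moving the dip much, so
   the dip no longer sits above the vertebral body. The contour is split
   into four sectors by two cross-lines — one through the dip parallel to
   the reflection axis, one perpendicular at distance *d* anterior of the
   dip — and each sector's area A, B (anterior right/left), C, D
   (posterior right/left) is the convex hull of its points evaluated by
   Gauss's shoelace formula. The lateral correction is

   x_off = ((A − B)/(A + B) + (C − D)/(C + D)) · R_ω,

   where R_ω is the remaining width between the dip and the intersection
   of the anterior-posterior cross-line with the contour on the side the
   imbalance points to. A symmetric contour gives x_off = 0; rotation
   toward the patient's right gives x_off > 0.

5. **Trajectory and fit.** Corrected per-level positions are assembled
   into a 3D trajectory; its coronal projection x(z) is fitted with a
   polynomial of user-chosen degree 1–7 (degree 2 ≈ C-type, 3 ≈ S-type).
   Reported alongside: included angles between curve normals at adjacent
   knots, the maximal lateral deviation from the endpoint chord, and the
   severity class (mild ≤ 10 mm, moderate 10–20 mm, strong ≥ 20 mm; Cobb
   bands 10–20° / 20–40° / > 40° are available for radiographic input).

6. **Curve matching.** Two trajectories (e.g. surface-derived vs.
   vertebral-body-derived) are compared by a rigid match: free coronal
   translation plus a rotation about the moving curve's centre point,
   bounded to (−45°, +45°) so an upside-down match is impossible. The
   *optimality value* is the minimised mean squared point distance
   (mm²); lower is better, and it grows with the internal twist between
   spinous processes and vertebral bodies.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `d` | 50 mm | dip-to-cross-line distance; proxy for the vertebral-body-to-skin distance δ, which is close to constant within a person, so one value per subject suffices |
| `trim` | 0.70 | fraction of point distances kept by the axis fit; operationalises "match where the pathological side is least distorted" |
| `search_window` | 0.40 | posterior arc fraction searched for the dip (avoids anterior indentations such as the umbilicus) |
| `depth_threshold` | 1 mm | minimal dip prominence; below it the slice is flagged |
| `degree` | 2 | coronal polynomial degree |
| `n_samples` | 50 | points per curve in rigid matching |
| `thickness` | 2 mm | slab half-width for point-cloud slicing |
| `max_gap` | 15 mm | largest tolerated contour edge; longer gaps mean a fragmented slice (e.g. an arm in the plane) |

## Design choices where the method description is open

* **Grouping of the offset formula.** The printed form of the correction
  is ambiguous about whether R_ω scales both normalised imbalances or
  only the posterior one. The default scales the sum — this is the only
  reading that is dimensionally uniform, vanishes exactly for symmetric
  contours in both terms, and stays bounded by 2·R_ω. The alternative
  (`grouping = "second-term"`) is retained for sensitivity analysis.
* **R_ω side.** Measured on the side toward which the raw imbalance sum
  points (ties go to the right).
* **Points exactly on a cross-line** belong to the +x / anterior sector
  (deterministic tie-break).
* **Included-angle knots.** Degree-2 fits have no inflexion point, yet a
  total curvature angle is clinically useful, so the knot set is
  {lower endpoint} ∪ {inflexions inside the range} ∪ {upper endpoint}; a
  straight line yields 0°.
* **Deviation baseline.** The chord joining the fitted curve's endpoints
  (a vertical baseline through the lowest marker is selectable). The
  chord makes the measure invariant under rigid coronal transforms.
* **Optimality definition.** "Related to the residuals" is made concrete
  as the mean squared residual distance after optimal alignment; the
  definition is echoed into every report. Absolute optimality values are
  therefore not comparable to other implementations — only their
  ordering is.
* **Matching correspondence.** Points are paired at equal normalised
  level rather than nearest-point: trajectories share the level axis, and
  level-locked pairing prevents the degenerate sliding matches that
  nearest-point correspondence admits. The centre of rotation is the
  sampled point at the middle of the moving curve's level range.
* **Rotation estimate geometry.** In `vertebral_rotation()` Q is the foot
  of the posterior perpendicular from the vertebral body P, so the
  rotation is α = atan(QR/PS); a rotation of ~23° with PS ≈ 59 mm
  produces a dip shift of ~25 mm, consistent with the clinical example
  this construction mirrors.
* **Severity band edges.** Deviation: 10 mm → mild, 20 mm → strong
  (following the printed ≤/≥ conventions). Cobb: band edges at 20° and
  40° go to the lower band; below 10° the classifier reports
  "no scoliosis".

## The synthetic torso: what it emulates, what it does not

Patient scans cannot ship with a package, so every stage is validated
against `generate_torso()`, a parametric stated world:

* **Shape.** Superellipse cross-sections (exponent 2.5, half-widths
  160 × 110 mm at mid-torso with a smooth barrel taper, height 450 mm),
  roughly an adult torso.
* **Spine.** The spinous-process line is a polynomial x(u) of the
  normalised height; the dip (a Gaussian indentation, depth 6 mm,
  σ = 5 mm) sits exactly on it. The *vertebral body* lies δ = 50 mm
  anterior of the back skin and is shifted laterally by δ·tan(ρ) at
  vertebral rotation ρ — the dip does not move with rotation, the body
  does, exactly the mechanism the offset correction targets.
* **Rotation signature.** Rotation ρ adds a posterior bump (rib hump) on
  the rotation side, amplitude `hump_scale`·sin(ρ) with a Gaussian
  lateral profile (centre 0.6·a, σ 0.13·a), and an equal-area anterior
  flattening on the opposite side. `hump_scale = 80` mm was calibrated
  once, at design time, so that the sector-area offset x_off tracks the
  true body–dip shift δ·tan(ρ) across ρ = 5–25°; this mirrors how the
  correction is calibrated against CT in practice and was frozen before
  any acceptance test was written.
* **Noise.** Gaussian vertex noise, default σ = 0.5 mm — the upper end
  of the surface accuracy a fused RGB-D scan achieves — with a fixed
  seed; generation is bit-reproducible.

A green test suite therefore establishes that the implementation recovers
*its own stated world*: embedded C-curves to a few millimetres, known
rigid transforms to 0.1 mm / 0.5°, repeat-scan spread below 5 mm, and
monotone responses of asymmetry, offset and optimality to increasing
simulated rotation. It does **not** establish clinical accuracy on real
torsos: real rib cages, breast tissue, soft-tissue asymmetries and
posture sway are absent from the generator, and the hump model is a
single-lobe caricature of a rib hump.

## Numerical notes

* Polynomial fits rescale z to [−1, 1] before solving the normal
  equations by QR; degree-7 fits on 400 mm torsos stay well conditioned.
  Inflexion levels are real roots of the second derivative inside the
  data range (imaginary tolerance 1e-8).
* The rigid match profiles the translation out in closed form; the
  remaining 1-D rotation objective is minimised by bounded L-BFGS-B from
  three starts (−30°, 0°, +30°). The objective is sinusoidal in the
  rotation, so this finds the constrained optimum; at a true relative
  rotation beyond the bound the optimiser sits at ±45°.
* Reflection uses exact Householder mirroring (an involution to machine
  precision); axis-contour crossings are linearly interpolated, including
  the degenerate case of a vertex exactly on the axis.
* Contours are oriented counter-clockwise; areas are absolute shoelace
  values, so point-order permutations cannot flip signs.
* Monte-Carlo area checks in the test suite use rejection sampling with
  10^6 points per polygon, independent of the shoelace code path.

## Known limitations

* The dip detector assumes one dominant posterior indentation; exotic
  contours with multiple deep dips keep only the deepest.
* The offset correction is empirical; its gain depends on torso shape,
  and `d` is constant per subject (level-dependent profiles are future
  work).
* Fragmented slices (arms, waist bands) are flagged, not repaired; mask
  them with `mask_box()` or drop the level.
* Severity classification from surface data is a surrogate — Cobb-band
  classification needs radiographic angles.
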