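---
title: "Estimating intraoperative spinal alignment from two tracked vertebrae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating intraoperative spinal alignment from two tracked vertebrae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinecurve)
```

## The model and its assumptions

`spinecurve` treats a spinal segment as a chain of rigid vertebrae. Each
vertebra `i` is reduced to its center of mass `CM_i` and the unit normals of
its two endplates, `n_Si` (superior, pointing cranially) and `n_Ii`
(inferior, pointing caudally), all in the scan's LAI frame (x = left,
y = anterior, z = inferior). Intervertebral discs and soft tissue are not
modelled: the package answers a geometric question (where are the untracked
vertebrae, given where the tracked ones are) rather than a biomechanical
one. That is the same simplification the intraoperative use case forces —
only rigid-body poses are observable without imaging.

Two vertebrae per estimation span carry optical-tracker rigid bodies. The
superior one, `VR_0`, is the fixed reference: every tracker pose is
re-expressed in its frame, so any motion common to the whole patient
cancels in the relative pose `(T_OTS,VR0)^-1 T_OTS,VRi` and anatomical-plane
angles remain well defined regardless of table position.

All curvature reasoning is strictly per-plane and 2D. The sagittal chart
takes (u, v) = (anterior, inferior), the coronal chart
(u, v) = (left, inferior); v is the "height" coordinate, increasing
caudally. Projected endplate normals are renormalized before use so that
distances measured along them are true in-plane distances; a normal nearly
perpendicular to a plane (projected magnitude below 1e-6) is a hard error
rather than a silently unstable direction.

## The four stages

**Curve estimation.** The in-plane spine shape is a Bézier curve anchored at
the projected tracked CoMs. `EN` uses only the two shaping normals: if the
ray from `CM_0` along the projected `n_I0` and the ray from `CM_{n-1}` along
the projected `n_S,n-1` intersect with both ray parameters positive, the
curve is the quadratic through the intersection; otherwise four control
points with `d_pos/4` offsets along the normals are used, which makes a
straight spine produce an exactly straight curve. The intersection test is
deliberately on *rays*, not infinite lines: the construction is only
meaningful when the normals meet between the vertebrae on the concave side,
and parallel or anti-parallel normals (the straight spine) must take the
four-point branch. We accept an intersection beyond the inferior vertebra
(a very large positive parameter); nothing in the construction breaks
there, though the resulting bow is extreme.

`ENIP` adds the preoperative CT spacing: each vertebra's chain fraction
`%d_i` — its cumulative share of the CT-time polyline length through the
CoMs — offsets one control point per vertebra along the nearer tracked
vertebra's normal ray. We read "total distance" as the polyline (chain)
length rather than the straight-line distance because the fractions are
accumulated over consecutive-CoM distances and must stay ordered for curved
spines; a `fraction_mode = "straight"` alternative (chord-projection
fractions) is available on `spine_segment()`.

**Position estimation.** `PE_H` places vertebra `i` at the curve point whose
height is `v_0 + %d_i h_t`; with several curve points at that height the
most cranial (smallest `t`) wins, which preserves the superior-to-inferior
ordering and is our explicit choice for non-monotone heights (possible only
for extreme shapes). `PE_P` erects perpendiculars to the tracked chord at
the fractions `%d_i d_pos` and intersects them with the curve, keeping the
root nearest the fraction itself. Perpendicularity is computed by rotating
the chord direction vector by 90° — never as the slope reciprocal
`m_p = -1/m`, which is undefined for vertical chords even though it is the
convenient way to *describe* the construction.

**Orientation correction.** `STV` turns each vertebra, from its
registration-time orientation, by the signed angle between the curve tangent
at `VR_0` and the tangent at the vertebra's own curve parameter. `IVN`
instead aligns the vertebra's intermediate endplate vector
`v_i = (n_Ii - n_Si)/2` (projected, from registration-time geometry) with
the local tangent. The underlying angle formula,
`arccos(a·b / |a||b|)`, yields only magnitudes; every correction's sign is
taken from the 2D cross product of (reference, target), the unique
orientation-consistent choice once a rotation direction is needed. The
composition onto *registration-time* orientation (never onto the previous
frame) makes repeated updates drift-free and makes the whole correction
pass the identity on a straight, unmoved segment. The direction convention
(reference → target rather than the reverse) only flips the global sign and
is fixed by the post-condition that rotating `v_i` by `θ_i` lands on the
tangent.

**Combination and feedback.** The per-plane angles `θ_s, θ_c` combine into
one rotation as the axis-angle exponential of the rotation vector
`[θ_s, θ_c, 0]` about the left/anterior axes. We prefer the rotation-vector
form because it is order-free and symmetric in the two planes; a fixed
x-then-y Euler composition is available (`rotation_method = "euler_xy"`)
and differs only at second order in the angles (about 3e-4 rad at 1°). One
chart subtlety is handled centrally: a counterclockwise angle in the
coronal (left, inferior) chart corresponds to a *negative* rotation about
the anterior axis, so `apply_corrections()` flips that sign when building
the rotation vector. The 3D CoM is reassembled from the two planar
estimates — coronal supplies left, sagittal supplies anterior, and the
duplicated inferior coordinate is averaged (the two planes are estimated
independently and may disagree by a small ε; averaging is the symmetric
reconciliation).

Alignment feedback is the angle between the superior endplate of the
superior vertebra and the inferior endplate of the inferior vertebra, for
every vertebra pair, folded to the acute line angle in [0, 90] — the
Cobb-style magnitude convention clinical tables use (published values up to
45° are consistent with either the line- or vector-angle reading; we chose
and document the line angle). The Δ column is `simulated - baseline`,
positive when an angle increased intraoperatively.

## Numerical choices

Bézier evaluation is in Bernstein form; curve/line and curve/height
intersections convert the (low-degree, ≤ 7) Bernstein polynomial to the
power basis and use `polyroot`, polishing each root with a bracketed
`uniroot` at 1e-9 in `t`. Residuals at returned roots are below 1e-7 in
signed distance. The parallel-line threshold is 1e-9 on the unit-direction
cross product. Cancellation residue in the leading coefficients (a
geometrically straight curve stored at higher degree) is trimmed at 1e-10
relative to the coefficient scale, which perturbs in-range values by far
less than the residual tolerance. When a perpendicular misses the curve
entirely, the default policy is graceful: the nearest curve point is used,
the vertebra is flagged, and a warning is logged with its label —
intraoperative streams should degrade audibly, not die; `strict = TRUE`
turns the fallback into an error.

## The eight evaluation methods

`enumerate_methods()` returns all 2×2×2 stage combinations as `M1`–`M8`.
The published description of the porcine experiment pins the mapping only
partially (M5–M8 use IVN; M8 is ENIP + PE_H + IVN; M6 is M8's PE_P
counterpart); the remaining placements follow that pattern (EN/ENIP
alternating, H before P within each orientation block) and are documented
as an assumption — all evaluation logic keys on the explicit triple, and
the labels are display sugar. One published RMSE comparison quoted for the
curve estimators (0.71° vs 0.70° preoperative coronal) is not fully
consistent with any single mapping and did not drive ours.

## What the phantom generator emulates — and what it does not

`generate_phantom()` mirrors the proof-of-concept configuration by default:
six vertebrae (four untracked intermediates between two tracked ends,
matching the evaluable porcine segment after its four fixation vertebrae
were excluded), 30 mm spacing (a typical lumbar CoM-to-CoM distance),
tangent-aligned endplates, no noise. Profiles: `straight`; `arc`, whose
vertebra tangents are spaced evenly over the total angle so that
consecutive-pair endplate angles are exactly `total/(n-1)` and the
tracked-pair angle is the total; and `V`, a kinked chain.
`simulate_correction()` reproduces the study's osteotomy protocol: it
rigidly rotates the sub-chain inferior to the apex (and the apex's own
inferior endplate) about the apex CoM and emits the OTS poses the tracked
pair would report, so the "surgical" path into the pipeline is exactly the
clinical one.

The phantom reproduces geometry, not physics: endplates are ideal planes,
noise is isotropic Gaussian (positions) and small random tilts (normals),
and discs, soft tissue, and segmentation error are absent. Passing the
recovery tests therefore shows the *geometric* pipeline is faithful —
arc-shaped spines with ≤ 30° curvature are recovered to within 2% of
`d_pos` in position and well under 1.5° in pairwise-angle RMSE by the best
method, and a 20° "V" degrades the sagittal RMSE to several degrees while
the coronal plane stays clean, the same qualitative failure mode the
porcine study hit (a single smooth Bézier cannot represent a kink). It does
not show robustness to registration error or tracker noise beyond the
modelled kinds. Ground truth is returned alongside, never inside, the
observable segment, so tests cannot leak it into the pipeline.

Problem sizes in the shipped tests and acceptance script (hundreds of small
phantoms, degree ≤ 7 curves, 1e4-sample oracle grids) were chosen to
exercise every branch while keeping the whole suite in seconds.

## The embedded porcine table

`poc_measurements()` returns the published per-pair angles of the porcine
experiment (manual readings, direct system readings, and M1–M8, pre- and
postoperative, both planes) with the printed RMSE column;
`poc_error_statistics()` recomputes every RMSE (population divisor over the
six pairs, against the manual row of the same phase and plane) and the
absolute-error extrema. Three internal inconsistencies of the publication
surface when doing so, and the package reports the recomputed values rather
than reproducing them: the preoperative M5 coronal RMSE prints as 0.71 but
its own six angles give 0.70 at print precision; the preoperative M7
coronal maximum absolute error is quoted as 1.11° at L3-L4 but the row's
maximum is 1.06° at L2-L3 (1.11° is the *M5* row's maximum); and the
postoperative coronal System minimum is quoted as 8.11° at L2-L3 while the
row's true minimum is 8.03° at L2-L4. The fixture checker
(`evaluate --poc-fixture`) flags exactly the first of these at its 0.01°
tolerance.

## Known limitations

- A single smooth curve per plane cannot represent sharp post-osteotomy
  kinks; the sagittal error after such an event is structural, not
  numerical.
- The intervened vertebra's own shape change is not modelled;
  `run_pipeline(intervened = ...)` only logs an auditable warning.
- Axial-plane rotation is out of scope (no standardized clinical metric),
  as are distance-based parameters (SVA/cSVA) and spinopelvic angles.
- Segments with more than two tracked vertebrae are treated as independent
  consecutive tracked spans, not fused globally.
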