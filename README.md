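# spinecurve

Radiation-free intraoperative spinal alignment estimation from two tracked
vertebrae per segment.

## The problem

During surgical correction of spinal deformities (scoliosis, abnormal
kyphosis/lordosis), the surgeon needs to know the spine's current alignment —
but the standard answers, fluoroscopy and intraoperative CT, cost radiation
and still leave the assessment largely visual. An optical tracking system
(OTS) can report the 6-DoF pose of a small number of instrumented vertebrae
without any imaging, yet clinical angle metrics need the orientation of
*every* vertebra in the segment.

`spinecurve` closes that gap for surgical-navigation researchers and
engineers. It models the spine as a chain of rigid vertebrae and estimates
the untracked ones from just two tracked vertebrae plus the preoperative CT
geometry:

1. **Reference-frame tracking.** The superior tracked vertebra `VR_0` is held
   fixed; every OTS pose is re-expressed in its frame,
   `T_rel = (T_OTS,VR0)^-1 T_OTS,VRi`, so patient repositioning on the table
   cancels exactly.
2. **Curve estimation.** In each anatomical plane (sagittal, coronal) a
   Bézier curve `C(t) = Σ B_{i,k-1}(t) p_i` is anchored at the tracked
   centers of mass (CoMs). Control points come either from the tracked
   endplate normals alone (`EN`: the normals' ray intersection, or four
   equally spaced points at `d_pos/4` offsets when they don't intersect) or
   from the normals plus the CT-time chain fractions `%d_i` of every
   vertebra (`ENIP`, one control point per vertebra).
3. **Position estimation.** Untracked CoMs are placed on the curve at their
   CT-time share of the tracked pair's height difference
   (`PE_H`: `y_i = y_0 + %d_i h_t`) or at the curve's intersection with
   perpendiculars to the tracked chord (`PE_P`).
4. **Orientation correction.** Each placed vertebra is rotated by a signed
   in-plane angle from the curve tangent `C'(t)`: relative to the superior
   tracked tangent (`STV`, `θ_i = ∠(t_0, t_i)`) or by aligning its own
   intermediate endplate vector `v_i = (n_Ii − n_Si)/2` with the local
   tangent (`IVN`, `θ_i = ∠(v_i, t_i)`). Sagittal and coronal corrections
   are combined into one 3D rotation via the rotation-vector exponential of
   `[θ_s, θ_c, 0]`.

The feedback surface is the clinical one: Cobb-style acute angles between
the superior endplate of the superior vertebra and the inferior endplate of
the inferior vertebra, for **all** vertebra pairs, in both planes, as
Baseline (registration-time) / Simulated (current) / Δ tables. The eight
compositions of the stage choices are the evaluation methods `M1`–`M8`
(`M8 = ENIP + PE_H + IVN`).

The package also ships a synthetic phantom generator with exact ground truth
(straight, circular-arc and post-osteotomy "V" segments) and the published
angle table from an ex vivo porcine proof of concept as an embedded fixture.

## Worked example

Simulate the proof-of-concept protocol on a phantom: a gently lordotic
6-vertebra segment (20° total arc, 4 untracked intermediates), a 15°
wedge-opening osteotomy at `V3`, and the tracker stream that motion produces.

```r
library(spinecurve)

ph  <- generate_phantom(phantom_spec(profile = "arc", total_angle = 20, seed = 42))
ev  <- simulate_correction(ph, "V3", wedge_sagittal = 15)
rep <- run_pipeline(ph$segment, ev$ots_poses, "M8")
rep$tables$sagittal[c(1, 5, 9, 15), ]
#>     pair baseline_deg simulated_deg delta_deg
#> 1  V1-V2            4          5.03     1.034
#> 5  V1-V6           20         35.00    15.000
#> 9  V2-V6           16         29.97    13.966
#> 15 V5-V6            4          3.22    -0.776
```

The tracked pair `V1-V6` reads the full 20° + 15° = 35° exactly (both ends
are measured, not estimated); pairs involving estimated vertebrae carry the
Bézier model's error. Scoring every method against the phantom's ground
truth reproduces the study's two key findings — IVN orientation correction
beats STV, and a kinked "V" spine defeats a single smooth curve in the
sagittal plane while the coronal plane stays clean:

```r
res <- evaluate_methods(ph$segment, ev$ots_poses, ev$truth$angles)
res[res$method %in% c("M1", "M8"), 1:5]
#>  method    plane rmse_deg min_abs_deg max_abs_deg
#>      M1  coronal     0.00           0        0.00
#>      M1 sagittal     7.95           0       15.77
#>      M8  coronal     0.00           0        0.00
#>      M8 sagittal     4.96           0        9.42
```

A shell interface wraps the same functions
(`exec/spinecurve phantom|estimate|evaluate|methods`), reading segment JSON
and pose-stream CSV files; `evaluate --poc-fixture` re-derives every RMSE of
the embedded porcine table from its own angle rows and reports PASS/FAIL per
cell.

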