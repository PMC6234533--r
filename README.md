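# kinsweep

Marker-set sensitivity analysis for constrained lower-extremity
kinematic models.

## The problem

Gait labs compute lower-extremity joint kinematics by fitting an
articulated, joint-constrained model of the pelvis and legs to
skin-mounted optical markers. Constraining the joints (a ball hip, a
single-degree-of-freedom "mobile-hinge" knee whose tibiofemoral
translations are prescribed functions of flexion, an oblique universal
ankle, a hinge forefoot) suppresses the dominant error source in optical
motion capture — soft-tissue artifact, the motion of skin markers
relative to bone. But it also raises a design question with real
workflow consequences: *how many thigh and shank tracking markers does a
constrained model actually need?* Each of the eight conventional
leg-tracking markers (three per thigh and shank plus the lateral knee
condyle and lateral malleolus) costs setup time and competes for skin
space with wearable sensors, braces and ultrasound probes.

kinsweep implements the full apparatus needed to answer that question:

* a self-contained constrained model with anatomic-landmark scaling
  (including an optional 1.3× mediolateral hip-center widening);
* fast per-frame constrained inverse kinematics: for each frame, the
  20-coordinate pose `q` minimising
  `sum_i w_i * || m_i_exp - m_i_model(q) ||^2` (compiled
  Levenberg–Marquardt, analytic chain Jacobian, warm starts, bounds);
* an unconstrained six-degree-of-freedom comparator (per-segment SVD
  rigid-body fits, floating flexion–adduction–rotation decomposition,
  anatomic-pose offset matching);
* the dropout sweep: constrained IK re-run for **all 2⁸ = 256 subsets**
  of the eight thigh/shank markers, scored against the full-set
  reference (RMS error, zero-lag cross-correlation `r_xy`, range-of-motion
  and peak deltas, joint-center displacement along lab AP/SI/ML axes);
* the statistics layer: 5° equivalence testing with paired t-tests,
  `r_xy > 0.90` fidelity labelling, subject-level bootstrap confidence
  bands, polynomial error-decay fits, and walking-speed comparisons;
* a synthetic treadmill-gait generator (Fourier gait templates with
  speed-calibrated ranges of motion, a segment-coherent soft-tissue
  artifact model calibrated so the IK-residual artifact proxy reproduces
  published per-marker magnitudes, measurement noise, gap injection)
  that carries exact ground truth for every trial;
* TRC marker-file reading/writing and YAML model/config serialization.

## Worked example

Simulate one subject walking 30 s at 1.2 m/s with realistic soft-tissue
artifact, run the pipeline, and compare the *simplified* marker set
(pelvis + lateral knee + lateral malleolus + shoes, bitmask `00010001`)
against the full set:

```r
library(kinsweep)

subject <- generate_subject(seed = 42)
gt <- generate_trial(subject, speed = 1.2, duration_s = 30,
                     artifact = artifact_model(sta_reference_targets("moderate")),
                     noise_sd = 0.3, seed = 7)
trial <- lowpass_filter(gt$trial)           # 6 Hz zero-phase Butterworth
strides <- detect_heel_strikes(trial, "R")
#> <stride_index> side R: 27 events, 26 plausible strides, median 1.120 s

ik_full <- constrained_ik(subject$model, trial)
#> <ik_result> 3001 frames, 28 tracked markers, 0 unconverged, mean residual 6.707 mm

round(sta_proxy(ik_full)[c("R.Thigh1", "R.LateralKnee", "R.Shank2", "R.LateralAnkle")], 1)
#>       R.Thigh1  R.LateralKnee       R.Shank2 R.LateralAnkle
#>           13.5           12.9            5.4            4.4
```

The `sta_proxy` values are the per-marker RMS distances between measured
and model-reconstructed trajectories — the standard surrogate for
soft-tissue artifact magnitude; here they reproduce the moderate-speed
calibration targets (13.5, 13.6, 5.5, 5.2 mm).

```r
simplified <- combination_from_mask("00010001")
sw <- run_sweep(subject$model, trial, combinations = list(simplified),
                strides = list(R = strides, L = detect_heel_strikes(trial, "L")))
sw$angles[, c("mask", "coordinate", "rms_deg", "r_xy", "rom_delta_deg")]
#>       mask         coordinate rms_deg  r_xy rom_delta_deg
#> 1 00010001        hip_flexion   1.175 0.998        -0.641
#> 2 00010001      hip_adduction   1.362 0.987         2.273
#> 3 00010001       hip_rotation   0.987 0.986        -0.579
#> 4 00010001       knee_flexion   1.350 0.999         2.325
#> 5 00010001 ankle_dorsiflexion   0.885 0.995         0.224
```

Dropping all six thigh/shank tracking markers changes joint-angle curves
by roughly a degree RMS with curve correlations above 0.98 — far inside
the 5° uncertainty band that soft-tissue artifact imposes on any
marker-based measurement, which is the quantitative sense in which a
constrained model is resilient to marker dropout. `run_sweep` with the
default `combinations = marker_combinations()` scores all 256 subsets;
`fit_error_decay` then summarizes mean error versus marker count
(joint-angle errors decay like a cubic; knee-center errors are several
times larger than hip/ankle and benefit most from the first two
markers), and `equivalence_test` / `speed_comparison` reproduce the
5°-threshold and speed-sensitivity analyses.

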