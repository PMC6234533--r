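---
title: "Constrained-model marker-dropout analysis: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained-model marker-dropout analysis: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

kinsweep asks a practical gait-lab question: when joint kinematics are
computed by fitting a *constrained* articulated model of the lower
extremity to skin-mounted markers, how much do the placement and number of
thigh and shank tracking markers actually matter? The package provides the
whole experimental apparatus in software: the constrained model, the
inverse-kinematics solver, an unconstrained six-degree-of-freedom
comparator, a sweep over all 256 thigh/shank marker subsets, the
statistics used to judge equivalence, and a synthetic treadmill-gait
generator that stands in for laboratory data.

This vignette records the scientific and numerical design decisions, in
the spirit of a lab methods section.

## The constrained kinematic model

The skeleton is a tree rooted at a 6-DOF pelvis (three translations in
mm; tilt-list-rotation orientation, a mobile Z-X'-Y'' sequence). Each
leg adds seven coordinates:

* **Hip** - ball joint: flexion about the pelvis Z axis, adduction about
  the floating X axis, internal rotation about the femoral Y axis
  (signs mirrored on the left so that positive adduction is always toward
  the midline).
* **Knee** - mobile hinge: a single flexion DOF about the femoral -Z
  axis. Tibiofemoral anterior-posterior and superior-inferior
  translations are *prescribed* functions of flexion, evaluated from a
  natural-cubic-spline knot table (anterior rollback growing to roughly
  18 mm and a superior shift of about 6 mm over 0-135 degrees,
  approximating published cadaver kinematics). Knee valgus and internal
  rotation are locked at zero by construction: skin artifact at the knee
  is larger than the true non-sagittal motion, so a constrained knee
  trades a small modelling bias for a large variance reduction. A
  `pure_hinge_knee` option zeroes the translations for exact-limit
  experiments. The knot table lives in the model object and is
  serialized with it; it is a configuration default, not a measurement.
* **Ankle complex** - oblique universal joint: talocrural dorsiflexion
  about an axis close to mediolateral (default direction approximately
  (-0.105, -0.174, 0.979) in the shank frame) followed by subtalar
  inversion about an oblique anterosuperior-medial axis (approximately
  (0.787, 0.605, -0.121) in the foot frame). Both defaults come from the
  standard lower-limb model family and are configurable.
* **Forefoot** - hinge (toe dorsiflexion).

Lab frame: X anterior, Y up, Z to the subject's right; angles in degrees,
positions in mm. Twenty coordinates in total.

### Scaling

Each segment is scaled isotropically from a static neutral-pose capture
using the conventional landmark pairs: inter-ASIS distance for the
pelvis, ASIS-to-lateral-knee-condyle for the thigh,
condyle-to-lateral-malleolus for the shank, malleolus-to-toe for the
foot. Three of those pairs span a joint, so the distal factor is obtained
by solving a scalar quadratic along the chain rather than by a raw
distance ratio; the practical consequence is that a model regenerated
from its own static pose recovers factors of exactly one, and landmark
distances are reproduced exactly. An optional pre-scaling step widens the
generic hip centers mediolaterally by a factor of 1.3, reflecting the
observation that functionally determined hip centers sit about 30% wider
than in generic models.

## Inverse kinematics

Constrained IK minimizes, per frame,

$$\min_q \sum_i w_i \lVert m_i^{exp} - m_i^{model}(q) \rVert^2$$

over the 20 bounded coordinates, with equal marker weights by default.
The solver is a compiled Levenberg-Marquardt with an analytic chain-rule
Jacobian (axis cross lever-arm per ancestor joint, plus the spline
derivative of the prescribed knee translation), step clamping to the
coordinate bounds, and warm starts: frame one is initialized by aligning
the pelvis to its four markers with neutral joint angles, every later
frame starts from the previous solution. Defaults: step tolerance 1e-7,
gradient tolerance 1e-10, relative cost tolerance 1e-10, at most 100
iterations per frame; unconverged frames are flagged, never dropped.
These are implementation policy, chosen so that solving a trial backwards
changes converged angles by well under 0.01 degrees RMS (path
independence), at roughly 0.5-1.5 ms per frame.

Marker subsets requested by the sweep keep every leg observable through
the shoe markers, so even the empty thigh/shank subset is solvable; the
bounded optimizer plus warm starting regularizes near-degenerate
configurations, and convergence flags travel with the result.

The **soft-tissue-artifact proxy** is the per-marker RMS, over frames, of
the distance between the measured marker and its model-predicted position
at the converged solution - the standard full-marker-set surrogate for
artifact magnitude when no direct skeletal measurement exists.

## The unconstrained comparator

Each segment's pose is estimated independently per frame from its own
four-marker cluster (pelvis markers; three tracking markers plus the
distal-lateral joint marker for thigh and shank; the four shoe markers
for the foot) by the closed-form SVD rigid-body fit with reflection
correction. Joint rotation matrices (proximal pose)^-1 (distal pose) are
decomposed with the floating flexion-adduction-rotation sequence for hip
and knee - flexion axis fixed in the proximal segment, rotation axis in
the distal segment, adduction floating - which is algebraically the
mobile Z-X'-Y'' decomposition on the model's own (side-signed) axes. The
ankle is decomposed directly onto the model's oblique
talocrural/subtalar axis pair, because the comparator's coordinate
systems are deliberately mirrored from the constrained model; using a
Cardan triad there would introduce a purely conventional disagreement of
several degrees even on perfect data. Finally all angles are offset so
that at the anatomic (static) pose they equal the constrained model's
anatomic angles, giving a one-to-one comparison. Frames with adduction
within one degree of +-90 are flagged for gimbal proximity.

## Preprocessing

* **Gap interpolation**: per coordinate, a cubic spline through the
  observed samples (the `fmm` end condition, which reproduces cubic
  polynomials exactly); gaps longer than `max_gap` (default 10 frames)
  or touching a trial boundary are errors, never silently filled.
* **Filtering**: 4th-order Butterworth applied forward-backward (zero
  phase) at 6 Hz, the walking-gait standard; the signal is mean-centered
  and odd-reflection padded, so constants pass through exactly and edge
  transients stay out of the trial. Interpolation runs before filtering.
* **Heel strikes**: treadmill-style coordinate-based detection - local
  maxima of the anterior displacement of the heel marker relative to the
  pelvis origin (PSIS midpoint). The dominant stride period comes from
  the autocorrelation peak beyond 0.4 s; candidate maxima are thinned
  greedily (tallest first) with a minimum separation of 0.4 stride
  periods; stride durations outside 0.6-2.5 s are discarded. First and
  last partial strides are never used.
* **Time normalization**: each stride is linearly resampled to 101
  points (0-100% of the gait cycle, supporting fractional stride
  boundaries) and curves are averaged pointwise across strides.

## The dropout sweep

All $2^8 = 256$ subsets of {Thigh1, Thigh2, Thigh3, LateralKnee, Shank1,
Shank2, Shank3, LateralAnkle} are enumerated by cardinality then
lexicographic position, and encoded as an 8-character bitmask in that
fixed order (`"00010001"` is the *simplified* set: lateral knee + lateral
malleolus only). Both legs always share the subset, and pelvis and shoe
markers are always included. Every combination is re-solved with
constrained IK and its stride-averaged joint-angle and joint-center
curves are scored against the full-marker reference *from the same
trial*: per-coordinate RMS error, zero-lag cross-correlation, range of
motion and peak deltas, and joint-center RMS decomposed along the lab
anterior-posterior / superior-inferior / medial-lateral axes (treadmill
walking keeps subjects lab-aligned, so lab axes are used). Left and
right metrics are pooled by averaging. Failures are recorded with a
flag; no combination is skipped.

## Statistics

All thresholds live in one constants object (`kin_constants()`): the
5-degree equivalence threshold (the approximate uncertainty that skin
artifact imposes on marker-based kinematics), the 0.90
cross-correlation cutoff for "substantially different" curve shapes,
and alpha = 0.05. Cross-correlation is the zero-lag Pearson coefficient
of heel-strike-aligned curves; a max-over-lags variant (up to +-10% of
the cycle) is available behind an argument. Bootstrap confidence bands
resample subjects with replacement (default 2000 resamples, seeded) and
take pointwise percentile intervals; a BCa variant is provided, but the
percentile interval is the default because it is assumption-light and
transparent at these cohort sizes. Polynomial error-decay fits report
ordinary least-squares coefficients and R-squared, with R-squared
defined as 0 for a zero-variance response. The equivalence procedure
flags group-mean peak/ROM differences beyond 5 degrees, runs two-sided
paired t-tests only on flagged cases (deliberately without
multiple-comparison correction, favouring sensitivity over specificity),
and labels a coordinate high-fidelity only if nothing is flagged and its
curve correlation exceeds 0.90. Speed comparisons are paired t-tests
across the three belt speeds with `s`/`m` markers for significant
increases over the slow and moderate conditions.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which everything else is validated.

**Kinematic truth.** Joint-angle curves are low-order Fourier series
over the gait cycle with physiologically shaped harmonics; per
coordinate, the curve is rescaled so its range of motion hits a
speed-dependent target (hip flexion ~39/43/47 degrees at 0.9/1.2/1.5
m/s; knee flexion ~63-66; ankle ~22-29; hip adduction ~17-20; hip
rotation ~10-14 - values consistent with published normative treadmill
ranges, with ROM non-decreasing in speed for the speed-sensitive
coordinates). Stride time is 1.35 - 0.2 x speed seconds (about 108
strides per leg in a 2-minute 1.2 m/s trial), with 2% stride-to-stride
period jitter. Subjects add bilaterally symmetric anthropometric scale
factors (s.d. 0.05), per-coordinate ROM multipliers (s.d. 0.06),
baseline offsets (s.d. 2 degrees) and a phase shift. Heel-strike truth
is defined as the phase at which the noise-free heel-forward
displacement peaks, recorded by the generator for every stride.

**Soft-tissue artifact.** Displacements are applied in the segment frame
(they ride on the moving limb, as skin does) and are built from two
parts: a *segment-common* near-rigid field - one random phase-locked
harmonic pattern plus a slow AR(1) drift per segment, with amplitude
sqrt(0.8) times the smallest marker target on that segment - and a
marker-specific remainder of the same construction that tops each marker
up to its target RMS. The common/remainder split encodes the empirical
observation that skin moves as a smooth field, so most artifact energy
is shared by a cluster; modelling markers as independently noisy makes
single-marker subsets unrealistically bad. Default per-marker targets
are published artifact magnitudes for thigh (9-14 mm), lateral knee
(13-16 mm), shank (5-10 mm) and lateral ankle (5-6 mm) at each belt
speed; pelvis (6 mm) and shoe (4 mm) markers also carry artifact, since
real support markers are not artifact-free even though the sweep never
drops them. The AR(1) coefficient (0.985 at 100 Hz) keeps the drift
below the 6 Hz filter band.

**Calibration.** The quantities those published magnitudes actually are
is the IK-residual *proxy*, not raw displacement, and the chain fit
absorbs a marker-dependent 10-20% of whatever is injected. The default
calibration (`calibrate = "proxy"`) therefore runs up to four IK passes
on a calibration window and rescales each marker's *remainder* (damped,
exponent 0.7 - absorption couples markers on a segment) until the
pipeline-level proxy matches the target to within ~4-6%.
`calibrate = "injected"` instead makes the injected RMS exact.
Measurement noise is isotropic Gaussian (default 0.3 mm, sub-millimeter
tracking); optional gap injection exercises the interpolation path.

**What the generator does not emulate.** Camera geometry and occlusion
physics, marker relabelling errors, asymmetric or pathological gait,
non-stationary fatigue effects, and ground-reaction forces. Passing
tests on this generator demonstrate that the *pipeline* is correct and
that its conclusions hold under calibrated artifact of realistic
magnitude and structure - not that any specific laboratory cohort would
produce identical numbers.

## Problem sizes

The test-suite and the acceptance script use deliberately modest sizes
chosen as a balance of statistical resolution and turnaround: 10 s
noise-free trials for exact-recovery checks; a 2-minute slow-speed trial
for artifact-proxy calibration; full 256-combination sweeps on three
subjects with 20 s trials sampled at 50 Hz (6 Hz-filtered kinematics are
fully resolved well below 50 Hz); six-subject cohorts at three speeds
for the speed-sensitivity analysis; 120 simulations x 500 resamples for
bootstrap coverage. Each quantity scales up by changing one argument.

## Known limitations

* The generic model geometry is standard-anthropometry, not
  subject-imaged anatomy; the analysis concerns *relative* errors among
  marker sets, which is insensitive to moderate geometry changes.
* The knee knot table and ankle axis obliquities are configuration
  defaults from the literature, not fitted quantities.
* Whether the knee's prescribed translations are expressed in the
  femoral or tibial frame is a convention choice; the package uses the
  tibial (child) frame and documents it, since the source-model lineage
  admits either reading.
* The unconstrained comparator inherits each cluster's rigidity
  assumption; its foot cluster includes the toe marker, so forefoot
  motion bleeds into ankle estimates (a fraction of a degree in
  practice, zero when the forefoot is locked).
* The pooling of left/right legs assumes bilateral symmetry, which the
  generator enforces but real cohorts only approximate.
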