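---
title: "Validating monocular head pose against motion capture: models, choices and limits"
author: "headkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating monocular head pose against motion capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headkin)
```

This vignette is the package's own account of its methods: the models and
procedures it implements, the assumptions behind them, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the numerical and design choices made where the methodology was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Rotations and conventions

All orientation computation is carried out on 3×3 rotation matrices.
Matrices act on column vectors, and a head-pose rotation maps head-frame
coordinates into its reference frame, so its columns are the head axes
expressed in that reference frame. This makes the camera-to-global
conversion a plain left multiplication (section 3). Euler angles
(intrinsic z–y′–x″, i.e. yaw–pitch–roll, in degrees) exist only for
display; no metric or estimator uses them, because Euler errors depend on
the angle convention and break down at gimbal lock. Within 1° of gimbal
lock the decomposition sets roll to 0 and flags the output.

Validity is enforced, not silently repaired: a matrix qualifies as a
rotation when ‖RᵀR − I‖_F ≤ 1e−8 and |det R − 1| ≤ 1e−8. Data that fail
must be passed through `project_rotation()` (nearest rotation in
Frobenius norm, via SVD with the determinant sign enforced) explicitly,
so corrupt files surface instead of being patched over.

Two numerical choices deserve note. The logarithm map is evaluated
through the unit-quaternion parameterisation, and the geodesic distance
switches from `acos((tr−1)/2)` to the identity
θ = 2·asin(‖R₁ − R₂‖_F / (2√2)) when the angle is small: the trace–acos
formula loses half the significant digits near 0 and π, which matters for
exact-recovery tests at 1e−8–1e−10 tolerances. Both forms are the same
mathematical quantity. At an angle of exactly π, where the principal log
is two-valued, the axis whose first nonzero component is positive is
returned — an arbitrary but deterministic tie-break.

## 2. Reference orientations from markers

The anatomical coordinate system (ACS) is built from five markers on
skeletal landmarks. The Frankfort plane — through the inferior orbital
rims and the upper margins of the external auditory meatus — defines the
head's anatomical horizontal. The construction: origin at the EAM
midpoint; y the unit vector from EAM_R to EAM_L; the provisional anterior
direction points from the origin to the IOR midpoint (projected into the
plane orthogonal to y); z = a × y (superior); x = y × z (anterior).

`markers_to_rotseq()` prefers a per-frame orthogonal Procrustes fit of
the participant's reference geometry (estimated in ACS coordinates from
the first 10 frames) over the direct four-marker construction, because
the rigid fit uses all five markers — including the nasion, which exists
precisely to provide redundancy under occlusion — and averages isotropic
marker noise over five points instead of four. Both methods agree exactly
on noiseless data (a test asserts this), and the rigid fit reports an
RMSD that serves as a per-frame data-quality channel.

**Filtering.** "Fourth-order, zero-lag Butterworth" is interpreted as a
second-order filter applied forward and backward (net order 4), with no
cutoff-correction factor — conventions differ across biomechanics
software, so the choice is documented rather than assumed. Edge handling
uses odd-symmetric signal extension of three filter-order lengths with
steady-state initial conditions, which makes a constant signal an exact
fixed point and cancels phase lag to machine precision. The amplitude
gain at the cutoff is 0.5 (two passes of −3 dB), and the test suite
asserts it.

**Cutoff selection.** Residual analysis computes the RMS difference
between raw and filtered signal over a cutoff grid, fits a straight line
to the high-frequency tail of that curve — taken as the upper half of the
grid, since the method's classical description leaves the tail
unspecified — and estimates the noise floor as the line's zero-frequency
intercept; the chosen cutoff is the lowest grid value whose residual does
not exceed the intercept. On noiseless signals the intercept is
essentially zero and the rule degenerates (any real filter leaves a small
transition-band residual), so the tests assert the noise-floor recovery
property (intercept within 20% of a known injected noise RMS) rather than
an idealised brick-wall behaviour. The FFT check returns the highest
frequency whose one-sided magnitude exceeds 10% of the peak non-DC
magnitude; fraction-of-peak was chosen over fraction-of-cumulative, and
the choice is isolated behind one function.

**Windows.** The impact window is half-open, [impact − 20 ms,
impact + 80 ms), which is the only convention under which a 1000 Hz
recording yields exactly 100 frames and a 50 Hz video yields exactly 6
— the sixth video frame falls on the window boundary and is clamped to
the nearest in-window sample (index 99). A closed window cannot reproduce
both counts simultaneously.

## 3. Anatomical alignment

Predictions arrive in the camera frame and with the model's own notion of
the head axes. The frame is fixed by R̂_HG = R_GC·R̂_HC. The axis
mismatch is a constant rotation D, estimated from the framewise relative
errors δᵢ = R̂ᵢᵀRᵢ as their Karcher mean on SO(3) — the point minimising
the sum of squared geodesic distances — computed by iterative
tangent-space averaging (μ ← μ·exp(meanᵢ log(μᵀδᵢ))), initialised at the
first element and declared converged when the tangent-mean norm falls
below 1e−9 rad (quadratic convergence inside the uniqueness ball; inputs
dispersed beyond a geodesic radius of π/2 are rejected because the mean
is then not unique). Aligned predictions are R̂ᵢ·Δ̂.

The composition side is the one detail on which printed conventions are
easy to transpose, so it is pinned by an algebraic test rather than by
notation: if R̂ᵢ = Rᵢ·D exactly, then δᵢ = Dᵀ, the Karcher mean is Dᵀ,
and R̂ᵢ·Δ̂ = Rᵢ recovers the reference exactly — asserted to 1e−8 for
offsets up to 40°. One offset is estimated per trial-camera sequence
(N = 6 frames), matching the design in which a single alignment rotation
serves a whole video sequence.

`fit_alignment()` returns a classed model object (`pose_alignment`) with
`print`, `summary`, `coef` (axis–angle of the offset), `predict` (apply
the offset to new sequences), `residuals` (per-frame GE after alignment,
degrees) and `plot` methods, because the offset estimate *is* a fitted
model: the estimator of a one-parameter (three-degree-of-freedom) group
element under noise.

Whether smoothing should precede alignment is not determined by the
methodology; both orders are supported (`order` in the run config) and
the default is smooth-then-align, which lowers the variance of Δ̂ at the
six-frame sequence length.

## 4. Temporal smoothing

Smoothing respects the group structure: rotations are mapped to the
tangent space at a base point, convolved per component with a discrete
normalised Gaussian (σ in frames, kernel half-width ⌈4σ⌉), and mapped
back. The base point is the sequence Karcher mean — a single chart is
adequate because window excursions stay well inside it; if the base-point
mean fails (pathologically dispersed input), the identity chart is used
with a warning. At the sequence edges the truncated kernel is
renormalised rather than padding the signal: with six-frame sequences,
reflection or replication padding distorts more than it preserves. σ = 0
is an exact identity; constant sequences are fixed points for every σ;
and on a shared rotation axis the whole procedure collapses to scalar
convolution of the angle series (tests assert all three).

The σ-sweep smooths, aligns, and pools mean GE and mean IGE over supplied
trials for each candidate σ; the selected σ minimises, by default, the
sum of mean GE and mean IGE in degrees (the methodology says the chosen
evaluation "metrics", plural, without a combination rule — the objective
is a config option `ge`/`ige`/`sum`, and both curves are always
reported). Ties break toward smaller σ. Reference widths for the built-in
profiles are 1.5 frames (face-driven) and 0.5 frames (body-context),
beyond which genuine motion is attenuated.

## 5. Error metrics

GE is the angle of RᵀR̂; IGE compares consecutive-frame rotation
magnitudes between reference and prediction. Two structural facts carry
most of the test weight: GE is bi-invariant (unchanged by a common change
of global frame), and IGE is invariant to *any* constant left or right
composition on either sequence — consequently identical before and after
anatomical alignment, which the suite asserts to 1e−9. All reported
values are degrees; radians are used internally.

Summaries pool frames, not per-trial means of means; per-trial summaries
are also produced because the paired front-versus-side comparison needs
one value per trial per camera. The first frame of every sequence is
excluded from incremental analyses (an increment needs a predecessor).
Under iid tangent noise with per-axis σ, the mean GE converges to
σ·2√(2/π) (the chi distribution with 3 degrees of freedom); this closed
form calibrates the generator and is verified at 10⁵ frames within 2%.

## 6. Detection and visibility

Boxes are continuous (x, y, w, h) with top-left origin and area w·h — no
+1 pixel convention, making the code annotation-tool agnostic. Matching
is greedy in descending IoU with a 0.3 success threshold; with one
participant per frame greedy matching is optimal, and a brute-force
assignment oracle covers the small multi-box cases. Precision, recall and
F1 are defined as 0 when their denominators vanish. The visible face area
subtracts the exact union of occluder boxes (coordinate compression —
overlapping occluders are not double-counted), and the visibility ratio
normalises by the per-camera maximum over the dataset; per-camera rather
than per-participant normalisation was chosen where the methodology is
ambiguous, switchable in config.

## 7. Statistical battery

Everything downstream is nonparametric, mirroring heavy right-skew in
pose-error distributions; the Shapiro–Wilk gate documents the skew.
Wilcoxon signed-rank (paired, front vs side, on per-trial means) and
Mann–Whitney U (unpaired, linear vs rotational) delegate to
`stats::wilcox.test` — exact null distributions for small untied samples,
normal approximation with tie correction otherwise — but correctness is
asserted by exhaustive enumeration oracles in the tests (all 2⁶ sign
assignments; all C(6,3) group assignments), not by trust in the library.
The reported U statistic is U_a (a-over-b pairs plus half ties). Cliff's
δ is computed exactly over all pairs. Bland–Altman limits use the
linear-interpolation percentile rule (`quantile` type 7) at 2.5%/97.5%,
with the median as bias; the rule is documented because nonparametric
limits admit several percentile definitions. Raw p-values are reported
with no multiple-testing correction, and the output metadata says so.
Both rank tests are verified to hold their nominal α = 0.05 level within
[0.03, 0.07] under 2000 seeded null replicates.

Paired front-versus-side comparisons use per-trial mean errors (the same
header seen by both cameras is the natural pairing unit); per-frame
pairing is statistically dubious across cameras and is not the default.

## 8. The synthetic study

The generator replaces an unavailable participant dataset, so its
defaults are the study conditions, chosen once:

- Design: 10 participants × (5 linear + 5 rotational) headers × 2
  cameras (frontal at (5.0, −0.4, 2.6) m, side at (−0.1, 3.0, 0.9) m,
  oriented 90° apart in yaw); 1000 Hz motion capture, 50 Hz video,
  1280×720 px; impact at 100 ms of a 300 ms recording; 20/80 ms window.
- Kinematics: a C²-smooth flexion pulse peaking 40 ms after impact with
  amplitude drawn uniformly from 22–36°; rotational trials add a smooth
  yaw ramp reaching 45° at the window end; a small (≤ 2°) roll. The
  22–36° band describes the flexion excursion; rotational trials
  necessarily exceed it once the yaw ramp develops, so the band check in
  the tests applies to linear trials and the yaw endpoint is checked
  separately.
- Markers: an invented but Frankfort-consistent head-frame geometry
  (EAM/IOR coplanar), a smooth forward head path, and 0.3 mm isotropic
  noise — a typical optical-capture residual; the marker-to-orientation
  closure test demands mean recovery error below 0.5°.
- Anatomical offset: a constant 15° rotation per model profile about a
  seeded random axis — the quantity the alignment stage must recover.
- Visibility: each trial draws an occlusion severity (a uniform 0–1.3
  multiplier on the reference dip depth 0.7, clamped at 0.95). The dip is
  asymmetric — fast onset as the ball arrives, slower recovery while ball
  and arms clear the face — and the trial's baseline visibility is tied
  to its dip depth, because the ball path, arm carriage and camera angle
  that produce a deep dip at contact also obstruct the face throughout
  the window; small per-frame arm flutter and, on the side camera, a
  yaw-dependent self-occlusion factor complete the model. Boxes realise
  each frame's target area exactly, so the visibility pipeline can be
  validated end to end from the emitted annotations.
- Prediction noise: right-composed (body-frame) tangent noise with
  per-axis standard deviation σ0 + σ1(1 − v); right composition makes
  the chi-3 closed form exact. The three profiles (σ0, σ1) =
  (2°, 25°), (2.5°, 12°), (2.5°, 1.5°) are calibrated to the magnitudes
  reported for face-driven and body-context estimators — severe
  degradation below 0.2 visibility for the face-sensitive profile,
  single-digit errors throughout for the body profile. An optional AR(1)
  correlation for the occlusion component exists (real estimators fail
  coherently while an occluder passes) but the default conditions are
  iid.

**What passing tests show, and what they do not.** The generator's noise
is synthetic: it has no systematic time-varying anatomical drift, no
detector failures that swap targets, no rolling-shutter or calibration
error, and its occlusion model is rectangles rather than silhouettes.
Tests against it demonstrate that the pipeline's estimators recover known
parameters under the stated noise model and that every metric has its
claimed invariances — they do not certify accuracy numbers for any real
estimator on real footage.

**Stratified analyses.** One analysis choice is worth its own paragraph:
the visibility-binned and per-time-step tables are computed from aligned
but *unsmoothed* errors. With six-frame windows, a σ = 1.5 Gaussian
kernel redistributes error mass across neighbouring frames; stratifying
the smoothed errors by a single frame's visibility then measures kernel
mixing rather than the estimator's frame-level sensitivity (empirically,
it flattens and even inverts the visibility relation regardless of the
noise level). Pooled summaries and the statistical battery use the full
smooth-then-align pipeline; the stratified tables isolate the per-frame
structure. Both error tables are written by `run_evaluate()`.

## 9. Problem sizes and determinism

The test suite and acceptance script use the full default design (200
trial-camera records per model profile) for pooled summaries, visibility
bins, and profile ranking; Monte-Carlo checks use 100–2000 replicates
with sizes chosen to keep each check's sampling error an order of
magnitude below the tolerance it asserts (500 replicates for offset
recovery at the six-frame sequence length; 10⁵ frames for the chi-3
calibration at 2%; 2000 replicates for test-level calibration;
one-participant datasets per seed for the 100-seed temporal-peak
majority). Every random draw descends from a single integer seed; the
same seed regenerates every file byte-identically, and a test asserts
it.

## 10. Known limitations

- The Karcher-mean alignment assumes the anatomical offset is constant
  within a sequence; slow drift between model and experimental axes is
  absorbed into the error term, and the single best fit centres on the
  middle frames, pushing residual error toward window boundaries (the
  U-shaped time profile the stratified tables display).
- Smoothing at σ ≳ half the sequence length flattens genuine motion;
  with six frames the practical range is σ ≤ 2.
- The residual-analysis intercept rule needs a noise floor to find;
  on nearly noiseless signals the chosen cutoff is grid-dependent.
- Angular velocity and acceleration are out of scope: 50 Hz video is too
  coarse for differentiating orientation, and the metrics deliberately
  stop at orientation and its first increments.
- Rectangular occluders understate complex occlusion geometry; the
  visible-area computation is exact for the boxes it is given, not for
  the scene.
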