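# headkin

Validation of monocular (video-based) head-pose estimates against
marker-based motion capture, for sports biomechanics and head-impact
research.

## The problem

Quantifying head acceleration events — such as football headers — from
ordinary video requires knowing how accurately a pose estimator recovers
head *orientation* under conditions those models rarely see: large, rapid
rotations and heavy occlusion by the ball, hands and arms. Validating an
estimator against optical motion capture raises a chain of methodological
questions this package answers with tested, reusable code:

- **Reference orientations.** A five-marker set on skeletal landmarks
  (left/right external auditory meatus, left/right inferior orbital rim,
  nasion) defines a Frankfort-plane anatomical coordinate system: origin
  at the EAM midpoint, y pointing left, z perpendicular to the Frankfort
  plane, x anterior. Marker trajectories (1000 Hz) are low-pass filtered
  with a fourth-order zero-lag Butterworth filter whose cutoff is chosen
  by residual analysis and cross-checked against an FFT magnitude
  threshold; orientations come from the direct construction or a
  least-squares rigid fit (orthogonal Procrustes) using all five markers.
- **Frame conversion and anatomical alignment.** Camera-frame predictions
  R̂\_HC are moved to the global frame with the camera extrinsics,
  R̂\_HG = R\_GC · R̂\_HC. The constant offset between the model's idea of
  the head axes and the experimental anatomical frame is estimated as the
  Karcher (Fréchet) mean on SO(3) of the framewise relative errors
  δᵢ = R̂ᵢᵀRᵢ and removed by a constant right-composition — one offset
  per trial-camera sequence.
- **Temporal smoothing.** Per-frame predictions are smoothed on the
  rotation group: log-map to the tangent space at the sequence mean,
  Gaussian convolution per component (σ in frames), exp-map back.
- **Error metrics.** Geodesic error GE = arccos((tr(RᵀR̂) − 1)/2), the
  minimal angle separating reference and prediction, and incremental
  geodesic error IGE = |d(R\_prev, R) − d(R̂\_prev, R̂)|, which measures
  frame-to-frame tracking fidelity and is provably blind to any constant
  offset (and hence to the alignment step).
- **Occlusion and statistics.** Detection quality (IoU at a lenient 0.3
  threshold, precision/recall/F1), an exact visible-face-area computation
  against annotated occluder boxes, visibility ratios normalised per
  camera, and a nonparametric battery: Shapiro–Wilk gate, Wilcoxon
  signed-rank (front vs side camera), Mann–Whitney U (linear vs
  rotational headers), Cliff's δ, and Bland–Altman summaries with median
  bias and nonparametric 95% limits of agreement.

Because the underlying participant dataset is not public, the package
includes a fully seeded synthetic heading-trial generator
(`generate_dataset()`) that emulates the study design — 10 participants ×
10 headers × 2 cameras, 100 ms windows with six 50 Hz video frames and
100 motion-capture frames, 22–36° flexion excursions, a known constant
anatomical offset, and visibility-dependent prediction noise with an
occlusion dip at ball contact — so every processing stage has an exact
parameter-recovery test.

## Worked example

```r
library(headkin)

cfg <- sim_config(n_participants = 2, trials_per_type = 2, seed = 42)
ds  <- generate_dataset(cfg, markers = FALSE)

# one trial: move camera-frame predictions to the global frame, then
# estimate and remove the anatomical offset
rec <- ds$records[[1]]
pred_global <- camera_to_global(rec$predictions$body_low, ds$extrinsics$F)
fit <- fit_alignment(rec$reference_video, pred_global)
fit
#> Anatomical alignment (Karcher mean of framewise relative errors)
#>   offset: 14.490 deg about axis (-0.582, 0.201, -0.788)
#>   frames: 6; mean GE 14.984 -> 3.908 deg; 4 iterations
```

The fitted offset (14.49°) recovers the generator's true 15° anatomical
offset from six noisy frames; removing it drops the mean geodesic error
from 14.98° (dominated by the coordinate-system mismatch) to 3.91° (the
prediction noise itself). `coef()`, `summary()`, `predict()`,
`residuals()` and `plot()` work as for any fitted model object.

Evaluating the whole dataset pools errors per model profile:

```r
out <- run_evaluate(ds)
out$summary[, c("model", "mean_ge_deg", "median_ge_deg", "mean_ige_deg")]
#>           model mean_ge_deg median_ge_deg mean_ige_deg
#> 1      body_low        3.16          3.10         1.93
#> 2     face_high        8.04          7.56         4.11
#> 3 face_moderate        7.31          7.54         5.02
```

The body-context profile (low occlusion sensitivity) attains the lowest
mean GE; the face-driven profiles degrade with occlusion, which
`out$by_visibility` and `out$by_time` break down by visibility bin and by
20 ms time step across the pre-impact/impact/post-impact phases.

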