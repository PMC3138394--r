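---
title: "Subvolume-based rigid registration for repeat prostate MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subvolume-based rigid registration for repeat prostate MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In image-guided radiotherapy of localized prostate cancer, repeat pelvic MR
series must be aligned to a reference (pre-treatment) series — for daily
patient positioning or for response assessment. The prostate, however, moves
relative to the bony pelvis as rectal and bladder filling change, so a rigid
registration driven by the whole image is dominated by bone and body outline
and leaves the *target* misaligned by several millimetres, predominantly in
the anterior–posterior (AP) direction. Restricting the registration metric
to a subvolume around the prostate trades global anatomical agreement for
local precision; the question this package operationalises is how large that
subvolume should be. The candidate registration volumes are the delineated
prostate gland itself (RV0) and its isotropic 3-D expansions by 10, 20 and
30 mm (RV1–RV3), compared against full-grid registration.

A practical attraction of the subvolume *rigid* approach (as opposed to
deformable registration) is that the fitted transform is directly
interpretable as a couch shift.

## The model

### Transform

A rigid mapping parametrised by a versor (unit quaternion) $q$ and a
translation $t$ about a fixed centre $c$:

$$p' = R(q)\,(p - c) + c + t .$$

Six parameters are optimised: the versor vector part $(v_1, v_2, v_3)$, with
$w = \sqrt{1 - \lVert v\rVert^2}$, and the three translations (mm). The
centre is the centre of mass of the registration volume, which decorrelates
rotation and translation; it is held fixed.

### Metric

Repeat T2-weighted series of one patient are single-modality, so identical
anatomy has (nearly) identical intensity and a mean-square metric is
appropriate. With the registration volume $V$ defined as a binary mask on
the *moving* (reference) image,

$$ M(T) \;=\; \frac{1}{|V_{\mathrm{in}}|} \sum_{x \in V_{\mathrm{in}}}
   \bigl[\, m(x) - f(T x) \,\bigr]^2 , $$

where $m$ is the moving image, $f$ the fixed (follow-up) image sampled by
trilinear interpolation, and $V_{\mathrm{in}}$ the mask voxels whose mapped
point lands inside the fixed grid. Out-of-bounds points are dropped from the
sum rather than zero-padded — zero-padding manufactures spurious minima at
the volume edge — and the registration aborts if fewer than half the mask
voxels (configurable, `min_overlap`) remain in bounds.

Keeping the mask in moving space means the delineation is never resampled;
its voxel centres are mapped into the fixed image instead. The moving image
is the pre-treatment series because that is where the prostate is delineated
in the clinical workflow.

### Optimiser

Regular-step gradient descent: step a fixed length against the scaled
gradient; when the descent direction reverses (negative dot product with the
previous direction), multiply the step by a relaxation factor; stop when the
step underflows. The analytic gradient chains the intensity difference
through the image gradient of the fixed volume (central differences of the
trilinear interpolant, world-space step `gradient_delta_mm`) and the
derivative of the mapping with respect to the six parameters.

The versor components are weighted in step space so that one unit of scaled
rotation parameter displaces mask-surface points about as far as one
millimetre of translation (weight $= 0.7\,r_{\mathrm{RMS}}$, with
$r_{\mathrm{RMS}}$ the RMS radius of the mask about the rotation centre).
This physical-shift scaling matters in both directions: weighting rotations
too heavily leaves them stranded when the step length collapses during
translation homing (with a fixed weight of 100 a known 3° rotation was
recovered to only ~2.8°); weighting them too lightly destabilises rotations
of large registration volumes. With auto-scaling the same fixture recovers
to 0.25°.

The returned transform is the best-visited iterate, so the final metric
never exceeds the initial one. A result is `flagged` when the optimiser did
not converge or the final metric exceeds a configurable absolute threshold
(`flag_metric_threshold`, default `Inf`); registration failure without
non-convergence does occur in this protocol family, so study-level outputs
keep per-registration diagnostics (iterations, final metric, flags) to make
failed registrations discoverable without images.

### Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `max_step_mm` | 2 | mm | largest plausible per-iteration correction at organ scale |
| `min_step_mm` | 0.01 | mm | convergence well below voxel size |
| `relaxation` | 0.5 | — | standard halving on direction reversal |
| `max_iterations` | 400 | — | cap; exhaustion returns `converged = FALSE` |
| `rotation_scale` | auto | — | physical-shift scaling from mask extent (above) |
| `gradient_delta_mm` | 0.001 | mm | effectively the exact local gradient of the interpolant |
| `min_overlap` | 0.5 | — | floor on the in-bounds fraction |
| margins | 10, 20, 30 | mm | the RV1–RV3 expansions |

`gradient_delta_mm` is deliberately tiny: trilinear interpolants are
piecewise linear, so a small central difference equals the exact local
derivative, which is also what makes the gradient verifiable against finite
differences of the metric itself.

## Registration volumes

`expand_mask()` implements the margin expansion as a Euclidean distance
transform in millimetres (separable lower-envelope algorithm with per-axis
spacing), thresholded inclusively at the margin. On an anisotropic grid
(e.g. 1.17 × 1.17 × 1.7 mm) a "3-D margin" must be isotropic in world space,
not in voxels. Expansions are clipped at the grid boundary without error — a
30 mm margin plausibly reaches the edge of a pelvic field of view. Whether a
body-outline clip should also apply is unknowable from the protocol
description; we clip at the grid only.

## Precision evaluation

For each registered pair the precision measure is the centre-of-mass (COM)
distance between the prostate delineations:

$$ \Delta = \mathrm{COM}(\text{target prostate}) - T(\mathrm{COM}(\text{reference prostate})), $$

reported componentwise in (RL, AP, CC) mm and as a norm; clinically this is
the residual couch-shift error. Aggregation per registration volume:

* sample mean and SD (n−1) of each *signed* component and of the norm — the
  SD of signed components is the clinically meaningful precision, matching
  a mean-bar ± 1 SD presentation;
* a norm-improvement table versus full-volume registration
  (min/max/median/mean of `norm_full − norm_RV` per pair);
* one-sided variance F-tests, $F = s^2_{\text{full}} / s^2_{\text{RV}}$ with
  $p = P(F_{n-1,n-1} \ge F_{\text{obs}})$, per axis and for the norm. The
  tests mirror directional claims (variance reduction) and are not
  multiplicity-corrected; callers doing many comparisons should correct
  downstream;
* the fraction of pairs for which each volume gives the smallest norm, with
  ties broken deterministically toward the smaller volume — the
  conservative direction for the "smallest volume wins" conclusion.

The sampling unit is the image pair pooled across patients (n = patients × 3
at the default design); no outlier removal is performed — a failed
registration stays in the statistics, flagged.

## The synthetic phantom

No imaging data accompany this problem, so every stage is exercised on an
analytic pelvic phantom with *known* prostate motion:

* **Static anatomy** (identical across series): elliptic body outline,
  iliac/sacral/pubic bone shells (dark cortex, bright marrow), and a smooth
  patient-specific soft-tissue texture field (SD 12 intensity units, ~12 mm
  correlation length) standing in for fat planes and muscle. Texture is
  essential: against uniform tissue, long translations are nearly free and
  the metric develops far-away minima that real pelvic MR does not have.
* **Moving layer**: an ellipsoidal prostate (~20/18/19 mm radii, internal
  sinusoidal texture and a darker central zone) rigidly displaced per
  series, plus a peri-prostatic halo (15 mm, partial weight 0.4) that drags
  the neighbouring tissue texture along — real periprostatic fat moves with
  the gland rather than shearing at the capsule. The layer is evaluated
  analytically at back-transformed coordinates, so the ground-truth
  transform is exact and no resampling error enters the phantom itself.
* **Organ variability**: the rectum (radius ±35%, lumen intensity 50 ± 40,
  wall position shifting a few mm) and bladder (size ±20%, position
  shifting) change between series. The rectal wall's AP shift is partly
  coupled (factor 0.8 plus 1 mm independent noise) to the drawn prostate AP
  motion, because rectal filling is what pushes the prostate; this coupling
  is what lets intermediate registration volumes partially track the target,
  as they do in practice.
* **Motion model**: AP SD 4 mm, CC 2.5 mm, RL 0.5 mm, rotation SD 1° about a
  random axis through the prostate centre — AP-dominant anisotropy, the
  qualitative signature of prostate-versus-bone motion.
* **Noise**: Rician (magnitude of a complex-Gaussian-perturbed signal),
  default σ = 4 on a scale where soft tissue is ~90.
* **Determinism**: one seed fixes the patient bit-exactly; series masks are
  the reference delineation transported by the true transform.

What the phantom does *not* emulate: deformable prostate shape change,
bias fields and coil-sensitivity profiles, k-space artefacts, delineation
variability (an optional jitter is deliberately left out of the default
study: synthetic follow-up masks are exact, so phantom SDs exclude the
observer-variability component that inflates delineation-based measures on
real data), posture/couch differences (bony anatomy is exactly static). The
last point caps what full-volume registration error can look like in
silico: it equals the injected prostate-versus-bone motion, whereas on real
patients posture adds to it. Passing tests on the phantom therefore
demonstrate correct mechanics and the right *ordering* of precision versus
registration-volume size, not the clinical SD magnitudes themselves.

## Study orchestration

`run_study()` executes the full design — by default 10 patients × 3
follow-ups × {full, RV0, RV1, RV2, RV3} = 150 registrations — at a
96 × 96 × 60 grid whose spacing preserves a 449 × 407 × 204 mm pelvic field
of view (the full-resolution 384 × 348 × 120 grid is available by
configuration). Masked registrations evaluate every mask voxel; the
full-grid volume is sampled with a deterministic stride of 2 voxels per axis
(~1/8 of voxels), a standard metric-sampling density choice. A registration
that raises an error is recorded with the identity transform and flagged,
and the study continues. Registrations are independent, and the study is
bit-reproducible for a fixed seed on one platform.

## Numerical choices and degenerate inputs

* Voxel *centres* carry world coordinates; indices are 0-based in the
  geometry convention (`origin_mm` is the centre of voxel (0,0,0)).
* Trilinear sampling is in-bounds on the closed voxel-centre lattice;
  outside points return `NA` (sampling) or are dropped (metric).
* The distance-transform threshold is inclusive (`d ≤ margin`), with a
  1e-9 mm² guard against floating-point ties.
* Empty delineations, non-overlapping volumes, degenerate F-test samples and
  unpaired/incomplete study tables raise typed errors rather than returning
  silently wrong numbers; the study driver converts registration errors into
  flagged identity results.
* The optimiser is deterministic; all randomness lives in the phantom and is
  seed-controlled.
* NIfTI volumes are reoriented to RAS on load so array axes always mean
  x = RL, y = AP, z = CC; oblique affines are rejected rather than silently
  resampled.

## Known limitations

* Single-resolution optimisation by default; a very large initial
  misalignment (beyond the capture range of the mean-square metric) can
  converge to a wrong minimum — such runs are the reason the per-pair
  diagnostics and the QC flag exist.
* Rotation recovery against *resampled* (rather than analytically
  transformed) images is limited by the interpolation noise floor at coarse
  voxel sizes; validation fixtures for sub-degree assertions use ~2–3 mm
  voxels for this reason.
* COM distance scores translation error only; rotational misregistration
  about the prostate COM is invisible to it (as it is to a couch shift).
* The mean-square metric presumes a stable intensity scale between series;
  the phantom's 2% inter-scan drift is tolerated, but unnormalised
  multi-visit data with stronger drift would need intensity standardisation
  upstream.
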