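# subvolreg

Registration-volume size versus precision for rigid registration of repeat
prostate MRI.

## What this is for

When repeat pelvic MR series are aligned rigidly for image-guided
radiotherapy (daily positioning, response assessment), the prostate moves
relative to the bony pelvis with rectal and bladder filling, so a
registration driven by the whole image leaves the target misaligned by
several millimetres — worst in the anterior–posterior direction. Restricting
the metric to a subvolume around the prostate fixes this, and the fitted
rigid transform remains directly interpretable as a couch shift. This
package is for medical-physics / image-analysis work that needs to quantify
that trade-off: it implements the full pipeline — masked metric, optimiser,
margin-expanded registration volumes, precision statistics — plus a
synthetic pelvic phantom with known prostate motion so everything is
testable end to end without patient data.

## The method

Rigid transform (versor $q$, translation $t$, fixed centre $c$):

$$p' = R(q)(p - c) + c + t$$

Mask-restricted mean-square metric, with the registration volume $V$ a
binary mask on the moving (reference) image and $f$ the fixed image sampled
trilinearly:

$$M(T) = \frac{1}{|V_{\mathrm{in}}|} \sum_{x \in V_{\mathrm{in}}} [m(x) - f(Tx)]^2$$

minimised by regular-step gradient descent over the six parameters (step
shrinks by a relaxation factor on gradient-direction reversal, converges
when the step underflows). Registration volumes are the delineated prostate
RV0 and its isotropic world-space expansions RV1–RV3 (10/20/30 mm, exact
Euclidean distance transform with anisotropic voxel spacing), versus the
full grid. Precision per registered pair is the centre-of-mass distance
between the prostate delineations, $\Delta = \mathrm{COM}_{\text{target}} -
T(\mathrm{COM}_{\text{ref}})$; per-volume aggregation gives per-axis
mean/SD, norm-improvement tables, one-sided variance F-tests and
best-volume frequencies.

## Worked example

```r
library(subvolreg)

p <- generate_patient(phantom_config(seed = 5))
p
#> <patient_series> patient01: 4 series of 96 x 96 x 60 voxels
#>   series 0: prostate shift (0.00, 0.00, 0.00) mm, rotation 0.00 deg
#>   series 1: prostate shift (0.72, -3.71, 2.91) mm, rotation 0.60 deg
#>   series 2: prostate shift (-0.33, -3.96, -2.87) mm, rotation 1.00 deg
#>   series 3: prostate shift (-0.91, -2.06, 0.41) mm, rotation 0.89 deg

res <- register_rigid(p$volumes[[2]], p$volumes[[1]], p$prostate_masks[[1]])
res
#> <registration_result> converged after 13 iterations
#>   final metric 25.927 over 467 mask voxels (in-bounds fraction 1)
#> <rigid_transform> rotation 1.603 deg, translation (0.6922, -3.789, 2.801) mm about centre (1.388, 8.233, -23.34)
```

The prostate of series 1 was displaced by (0.72, −3.71, 2.91) mm; the
RV0-masked registration recovers (0.69, −3.79, 2.80) mm. The residual
couch-shift error is the COM distance:

```r
com_distance(res, p$prostate_masks[[1]], p$prostate_masks[[2]],
             pair_id = "patient01_pair1", registration_volume = "RV0")
#>           pair_id registration_volume delta_rl_mm delta_ap_mm delta_cc_mm norm_mm
#> 1 patient01_pair1                 RV0      -0.127       0.139      0.0858   0.207
```

0.2 mm residual, against ~4.8 mm of injected motion. A whole study (here 3
patients for brevity; the default is 10):

```r
report <- run_study(study_config(n_patients = 3, seed = 42))
report
#> <study_report> 45 registrations, 3 patients
#>   AP SD RV0     0.12 mm (n = 9)
#>   AP SD RV1     0.99 mm (n = 9)
#>   AP SD RV2     3.05 mm (n = 9)
#>   AP SD RV3     3.65 mm (n = 9)
#>   AP SD full    3.46 mm (n = 9)
#>   most precise volume: RV0 for 78% of pairs
#>   flagged registrations: 0
```

AP precision degrades as the registration volume grows — the larger volumes
include more of the changing rectum/bladder and of the static anatomy that
the prostate moves against. `tidy(report)` returns the per-pair distance
tibble, `glance(report)` a one-row summary, `autoplot(report)` the
mean ± 1 SD bar chart per axis and volume.

A thin CLI covers the same operations from a shell
(`exec/subvolreg phantom|expand-mask|register|study`).

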