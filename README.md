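# livernav

Computational pipeline for electromagnetically (EM) tracked surgical
navigation in open liver surgery, exercised end-to-end on synthetic
phantoms with known ground truth.

During open liver resection the organ is mobilized and manipulated
continuously, so a static preoperative model is of limited use for
guidance. The system implemented here tracks the liver with a single 6-DoF
EM sensor fixed to its surface near the target tumor and treats the
surrounding region as **locally rigid**: the sensor's live pose change,

```
T_track(t) = pose(S_live(t)) ∘ pose(S_ref)⁻¹ ,
```

is applied rigidly to the whole anatomical model, and guidance accuracy is
claimed only inside a *target navigation zone* of radius 50 mm around the
sensor. The model reaches EM space through a registration chain

```
model (MRI) ──T1──▶ CBCT ──T23──▶ EM ,      ribs: CT ──T4──▶ CBCT
```

with **T1** an ROI-restricted alignment around the target lesion (manual
pass-through or automated mutual information), **T23** a least-squares
rigid fit (cross-covariance SVD) of six disc-shaped 5-DoF tracker-sensor
centers detected in the cone-beam CT (CBCT) against their live EM
positions — minimizing the RMS error of the six points, reported as the
fiducial registration error FRE — and **T4** a bone-masked,
center-of-mass-initialized mutual-information registration that places the
rib model for rib-relative motion display.

Because no clinical data ships with a pipeline like this, the package
includes a first-class phantom module: parametric liver/tumor/vessel/rib
scenes with four surgical clips, three patient trackers (six disc sensors)
and the liver sensor; CT/CBCT/MRI-like volume rendering including the
truncated-projection CBCT field of view; a deformation/breathing model
whose local displacement field is attenuated to zero inside a rigid core
around the sensor; and noisy 10 Hz EM pose streams. Every landmark's true
position is queryable at any time, so target registration error (TRE) can
be measured everywhere — including outside the navigation zone, where the
semi-rigid assumption is deliberately violated.

## Worked example

```r
library(livernav)

scene <- generate_scene(scene_config(), seed = 1)
scene
#> phantom_scene: 1 tumor(s), 4 clips, 6 disc sensors, 6 ribs (t = 0.00 s)

# Phase-I style clip registration: clip centers in the CBCT matched to
# their (here: noise-free) EM-space positions
src  <- landmark_in_image(scene, scene$clips, "liver", "CBCT")
live <- scene_points_em(scene, scene$clips, "liver")
r <- register_points(fiducial_set(src, live, frame_src = "CBCT", frame_dst = "EM"))
r$transform
#> rigid_transform: CBCT -> EM
#>   rotation 8.000 deg, translation (10.617, -9.515, 5.454) mm
r$fre
#> 2.22e-14  (exact correspondences -> zero residual)

# Full pipeline: render CT + truncated CBCT, detect the six disc sensors,
# build T1/T23/T4, replay a noisy EM stream, measure TRE against ground truth
rep <- run_pipeline(run_config(seed = 7, sigma_pos = 0.5, sigma_rot = 0.3))
rep$t23_fre_mm                 # 0.66 mm  six-point registration residual
rep$disc_detection_error_mm    # 0.10 mm  disc localization vs ground truth
rep$t4$translation_error_mm    # 0.17 mm  bone-MI registration error (0.13 deg)
rep$tre$mean_in_zone_mm        # 3.45 mm  end-to-end in-zone tracking error
```

The in-zone TRE of a few millimetres is the realistic end-to-end figure
for this design under vendor-class EM noise (0.5 mm / 0.3°); with
noise-free streams and exact registration inputs the same chain tracks
rigid motion with error ~1e-13 mm at every model point, i.e. the tracking
algebra itself adds nothing to the error budget.

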