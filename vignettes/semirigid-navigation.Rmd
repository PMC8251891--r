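---
title: "Semi-rigid EM navigation for open liver surgery: models, phantoms and accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-rigid EM navigation for open liver surgery: models, phantoms and accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(livernav)
```

## The problem

Open liver surgery moves the organ continuously: the surgeon mobilizes,
lifts and rotates the liver while resecting. A navigation system that shows
the tumor and vessels on a preoperative model is only useful if that model
follows the organ in real time. `livernav` implements the computational
pipeline of a cone-beam-CT (CBCT) plus electromagnetic (EM) tracking
navigation setup for this problem, together with a synthetic phantom world
in which every quantity the pipeline estimates has a known ground truth.

The tracking model is deliberately simple — and that simplicity is the
point. A single 6-DoF EM sensor is fixed to the liver surface near the
target tumor, and the liver region around it is treated as **locally
rigid**: whatever rigid pose change the sensor reports is applied to the
whole anatomical model. Guidance accuracy is claimed only inside a **target
navigation zone**, a sphere of radius 50 mm around the sensor (closed
boundary, `in_target_zone()`); outside the zone the model is still drawn
but flagged as non-accuracy-bearing.

## Coordinate frames and the registration chain

Everything in the package moves through named coordinate frames: `MRI`
(preoperative model), `CT` (preoperative rib model), `CBCT` (intraoperative
scan), and `EM` (tracker space, the world root). `rigid_transform` objects
carry mandatory frame labels that are checked at composition time — with
four frames and five transforms in play, a silent chain-order bug is far
more dangerous than a loud error. Conventions: column vectors, `y = R x + t`,
`compose_transform(A, B)` means *apply B first*; scalar-first unit
quaternions; mm everywhere; LPS axes.

The chain assembled by `build_chain()` is:

* **T1** (`MRI -> CBCT`): alignment of the model to the intraoperative
  scan, restricted to the region around the target lesion. Clinically this
  is a manual step; the package offers a validated manual pass-through and
  an automated surrogate (`register_roi()`, mutual information inside a box
  ROI).
* **T23** (`CBCT -> EM`): six disc-shaped 5-DoF sensor centers (three
  skin-mounted patient trackers, two discs each) are detected in the CBCT
  and registered to their live EM positions by least-squares point matching.
* **T4** (`CT -> CBCT`, optional): bone-to-bone mutual-information
  registration that places the rib model, used for rib-relative motion
  display (`rib_frame()`).
* **S_ref**: the liver-sensor pose saved at the moment of the CBCT
  acquisition (the stream sample nearest the declared snapshot time,
  matching the breath-hold convention).

Live tracking is then
`liver_tracking_transform(S_live, S_ref) %then% T23 %then% T1`: the rigid
transform that carries the sensor from its snapshot pose to its live pose,
applied to the whole model. The full 6-DoF pose drives the transform — the
system uses a 6-DoF (not 5-DoF) sensor precisely so that orientation is
observable; a translation-only ablation mode exists as a config flag.

## The phantom: what it emulates and what it does not

`generate_scene()` builds a deterministic ground-truth scene per
`(config, seed)`: a body ellipsoid, a liver ellipsoid with one or more
spherical tumors placed superficially, contrast-vessel tubes converging on
the lesion, six rib arcs, four surgical clips and the 6-DoF sensor on the
liver surface near the tumor (the sensor is required to sit within 50 mm of
the tumor surface; the generator places it at ~30 mm, the clinically
observed scale), and three posterior patient trackers whose disc pairs are
exactly 20 mm apart. The tracker layout deliberately sits at cylindrical
radius > 125 mm: visible only in the extended truncated-projection CBCT
reconstruction, exactly the geometry that forced the clinical system onto
truncated reconstructions.

`render_volume()` rasterizes a scene as a CT-, CBCT- or MRI-like volume by
tissue class (air −1000, soft tissue 50, liver 100, tumor 160, vessels 300,
bone ramped 700–1500, metal 3000) with additive Gaussian noise (default SD
10). These are ordinal Hounsfield-like classes, not CT physics: detection
and registration need contrast and structure, nothing more. Three rendering
choices matter downstream:

* metal is rendered via a signed-distance **coverage fraction**, emulating
  partial volume; this is what makes intensity-weighted centroids sub-voxel
  accurate;
* bone has a radial intensity ramp, so the within-mask histogram carries
  information for the MI metric;
* a CBCT render applies the fully-sampled Ø 250 mm × 200 mm cylinder: the
  standard reconstruction blanks everything outside it, the truncated
  reconstruction keeps the periphery but degrades it (5× noise, +30 bias) —
  usable for high-contrast tracker localization only.

The deformation model (`deformation_model()`) composes, for liver-attached
structures: a smooth local displacement field (sum of 3-D Gaussian kernels,
default length-scale 100 mm), a sinusoidal cranio-caudal breathing
translation (default 10 mm amplitude, 4 s period; the clinical protocol
suppresses it by breath-hold, which the simulator reproduces by sampling
the snapshot at a fixed phase), and a global rigid trajectory. Ribs, body
and trackers ride the global rigid trajectory only. The local field is
attenuated by a smoothstep to **exactly zero** inside a 30 mm rigid-core
radius around the sensor — the phantom's concession to the locally-rigid
assumption — and reaches full magnitude beyond twice that radius. Every
motion state keeps an invertible map to the reference state, so rendering
deformed scenes and querying true landmark positions stay exact
(the nonrigid inverse is a fixed-point iteration; displacement gradients
are far below 1, so it contracts).

What the phantom does **not** emulate: CBCT projection physics and
reconstruction artifacts (streaks, scatter, beam hardening), contrast
kinetics, EM field distortion near metal (noise is i.i.d. Gaussian,
σ_pos = 0.5 mm, σ_rot = 0.3°, vendor-class figures), tissue-dependent MRI
contrast, and physiological deformation patterns (the Gaussian-kernel field
is a smooth stand-in, not a biomechanical model). A green test suite
therefore says the *pipeline mathematics* is right under controlled
conditions; it does not certify clinical accuracy.

## Numerical choices

**Point registration.** `register_points()` is the closed-form
cross-covariance SVD solution with a determinant guard against reflections —
the global least-squares optimum, no iteration, no seed. Collinearity is
detected by the ratio of singular values of the centered source cloud
(threshold 1e-6) and reported with the unconstrained axis. Correspondence,
when unknown, is established by exhaustive search over permutations
(`match_correspondence()`, feasible to n = 8; ties break to the
lexicographically smallest permutation).

**Mutual information.** `register_mi()` samples the fixed volume at masked
voxels only (the mask is dilated by 2 voxels so the bone/soft-tissue
boundary contributes), builds a 32-bin joint histogram with
**partial-volume interpolation** (each sample distributes trilinear weights
over its 8 moving-grid neighbours), and maximizes MI with a 3-level
multi-resolution Hooke–Jeeves pattern search (initial steps 1 mm / 1° per
stride, halved to 0.02). Two design points were driven by observed failure
modes on phantoms: plain interpolate-then-bin histograms produce spurious
rotational local optima about a degree from the truth, which partial-volume
binning removes; and a center-of-mass initialization leaves the full
rotation to be recovered, where the repetitive rib arcs create distant
local optima — a deterministic coarse rotation-grid sweep (±10° in 5°
steps) before the search removes those. There is no random sampling
anywhere: identical inputs give bit-identical transforms.

**Detection.** Metal blobs are 26-connected components of supra-threshold
voxels (default threshold 2000, between the bone ceiling 1500 and metal
3000), size-filtered, with intensity-weighted centroids in world mm. Discs
(50–300 mm³) and clips (≤ 20 mm³) are disambiguated by component volume.
Disc pairs are grouped into trackers by exhaustive search over disjoint
pairings minimizing the summed deviation from the configured 20 mm pairing
distance; clips and other distractors fall out of the pairing geometry.

**Distances.** Pointer-to-tumor distance is the exact point-to-triangle
minimum over the transformed tumor mesh, with a bounding-sphere pruning
index; the un-indexed all-triangles scan is retained as the oracle the
index is tested against (1e-9 agreement). A tip inside the mesh (ray-parity
test) reports distance 0. On segmentation masks, the tumor "edge" is the
set of boundary voxel centers — a reproducible surrogate for the visually
judged edge.

**Accuracy statistics.** The accuracy measure per marker is
|d_nav − d_img|, with d_img the observer-averaged image distance; reported
as mean ± SD together with Pearson's R between the two distance sets and
its two-sided t-distribution p-value (n − 2 df). Degenerate inputs (n < 3,
zero variance) raise errors or are flagged rather than silently producing
numbers. `repeat_variability()` reports per-point ranges over repeated
measurements. `tre_profile()` bins target registration error by snapshot
distance from the sensor — the quantity the navigation-zone radius is
defined on, measurable on phantoms though not in patients.

## Problem sizes and what the checks show

Desk-scale runs use coarser grids than the clinical 0.66 mm reconstruction:
whole-body renders at 3 mm for MI registration (so "one voxel" there is
3 mm), a 1.5 mm whole-FOV scan for metal candidates, and 0.66 mm patches
around candidates for the actual localization measurements — the same
two-scale strategy a practitioner would use to avoid rasterizing a 500³
volume, with all measurements taken on full renders including noise, bone
and truncation degradation.

The headline properties verified by the test-suite and `scripts/acceptance.R`:

* a purely rigid phantom with noise-free streams is tracked with zero error
  (≈ 1e-13 mm) at **all** model points through the exact chain — the
  tracking algebra adds nothing to the error budget;
* the six-point solver recovers random transforms to 1e-6 and reproduces
  the FRE² expectation 3σ²(1 − 2/N) within a few percent;
* COM-initialized masked MI recovers random offsets up to 20 mm / 10°
  within a voxel and 0.5°;
* disc centroids are localized to ≈ 0.1 mm (≈ 0.15 voxel) at 0.66 mm
  spacing, and full-vs-truncated reconstructions of the same scene agree to
  well under one voxel — the geometric-distortion QC that justifies using
  the degraded periphery for tracker localization;
* under the attenuated deformation field (10 mm at 100 mm length-scale) the
  TRE is ~0 inside the rigid core and grows monotonically with distance
  from the sensor — the measured justification for restricting guidance to
  the navigation zone;
* with image-detected registration and vendor-class EM noise the end-to-end
  in-zone error is a few millimetres, which is the realistic system figure
  for this design.

## Known limitations

The rigid-core attenuation makes the in-zone tracking of the *phantom*
better than any real liver would allow — by construction the phantom's
deformation respects the assumption the system makes, except outside the
core where it deliberately violates it. The MI optimizer is a local search
with a bounded init sweep: offsets far beyond the tested 20 mm / 10°
capture range can fail, and `converged = FALSE` is reported rather than
guarded against. The exhaustive correspondence search is factorial and
capped at 8 points. MetaImage support covers LOCAL raw payloads only, and
STL reading merges coincident vertices (PLY is the lossless route).
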