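Package: livernav
Title: Electromagnetic Surgical Navigation for Open Liver Surgery on Synthetic Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for cone-beam CT (CBCT) and electromagnetically
    (EM) tracked navigation in open liver surgery, exercised end-to-end on
    synthetic phantoms with known ground truth. Provides rigid-transform algebra
    across named coordinate frames, a phantom generator (liver, tumors, vessels,
    ribs, surgical clips, disc-shaped patient-tracker sensors, a liver-surface
    6-DoF sensor, deformation and breathing trajectories, noisy EM pose streams),
    point-based fiducial registration with fiducial registration error (FRE)
    reporting, mutual-information rigid volume registration with bone masking and
    center-of-mass initialization, metal fiducial detection in CT/CBCT-like
    volumes, a semi-rigid organ-tracking model with a target navigation zone,
    and the accuracy-evaluation statistics of such a system (navigation-versus-
    image distance comparison, repeat-measurement variability, target
    registration error profiling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    RNifti,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
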