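Package: hiquant
Title: Quantification of Neonatal Hypoxia-Ischemia MRI and Evoked Field Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify experimental neonatal hypoxic-ischemic brain
    injury from multi-echo T2-weighted MRI and cortical slice
    electrophysiology. Provides voxelwise mono-exponential T2 relaxometry,
    hierarchical region-split segmentation of edematous tissue into ischemic
    core and penumbra by recursive histogram-valley thresholding, longitudinal
    lesion volumetrics with hemisphere-subtraction tissue loss, evoked
    field-potential metrics (input-output curve areas, paired-pulse
    facilitation), delta-delta-Ct expression fold changes, and a synthetic
    data module (multi-echo MRI phantoms with Rician noise and synthetic
    fEPSP sweeps) so that every stage is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    pracma,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
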