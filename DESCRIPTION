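Package: sodiumear
Title: Phase-Cycled bSSFP Sodium MRI Simulation and Inner-Ear Hydrops Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses phase-cycled balanced steady-state free
    precession (bSSFP) sodium (23Na) MRI of the inner ears. Provides a seeded
    digital temporal-bone phantom with endolymph/perilymph sodium compartments
    and controllable endolymphatic hydrops, a non-Cartesian (3D cones, radial,
    Cartesian) k-space forward model with off-resonance and T2* readout decay,
    gridding NUFFT and conjugate-gradient reconstruction over a frequency-offset
    sweep with F-state combination and root-sum-of-squares compositing,
    landmark-based thin-plate-spline fusion to structural imaging, and ROI
    quantification: median sodium signal scaled to the internal auditory meatus,
    between-ear ratios, a Likert-grade laterality decision rule, and two-way
    random-effects absolute-agreement intraclass correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
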