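Package: fretmd
Title: Single-Molecule FRET Binding Kinetics and Molecular-Dynamics Trajectory Observables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for camera-based single-molecule FRET binding
    trajectories of a DNA polymerase on primer-template DNA: a ground-truthed
    continuous-time Markov simulator of two-channel donor/acceptor traces,
    apparent-FRET computation and smoothing, anti-correlation screening and
    binding-event segmentation, Gaussian-emission hidden Markov state inference
    with transition density plots, time-binned FRET histograms with one- or
    two-Gaussian fits, dwell-time kinetics with censoring-aware dissociation
    rate estimation and relative stabilization energies, and linear trend fits
    against a solvent covariate. A companion set of coordinate-trajectory
    observables covers Kabsch superposition and RMSD, residue-wise dynamic
    cross-correlation and difference-correlation maps, radial distribution
    functions, tagged-site distances, and Cartesian PCA, with toy trajectory
    generators for testing every observable against analytic limits.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    minpack.lm,
    jsonlite,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
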