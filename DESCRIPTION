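Package: ommapol
Title: Ommatidial Alignment Analysis and Robust Polarization Vision Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the alignment of microvillar principal axes
    across hexagonal ommatidial arrays of compound eyes from depolarized
    eyeshine image stacks, and for modelling the consequences of misalignment
    for polarization vision. Provides seeded synthetic generators for eyeshine
    stacks, principal-axis fields, polarization image pairs, reflectance
    spectra and behavioural counts; ROI-grid photometry; Fourier-phase
    estimation of the principal axis from intensity-versus-rotation series;
    neighbour analysis classifying edge-detector chains and robust
    polarization-detector pairs; a two-channel polarization-opponent neuron
    model with second-order pairwise summation; degree-of-polarization and
    tetrahedral colour-space summaries of wing reflectance; and site-level
    behavioural statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'hex-lattice.R'
    'AllClasses.R'
    'AllGenerics.R'
    'synth-sigma.R'
    'synth-stack.R'
    'synth-misc.R'
    'photometry.R'
    'alignment.R'
    'hexarray.R'
    'opponent.R'
    'wingoptics.R'
    'behavior.R'
    'io.R'
    'pipeline.R'
    'utils.R'
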