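Package: focalsim
Title: Gaze-Contingent Defocus Simulation for Evaluating Vision Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An engine-independent simulator for evaluating vision correction
    methods on synthetic scenes. Models first-order ophthalmic optics (dioptric
    demand, residual accommodation, circle-of-confusion blur), renders
    depth-dependent defocus on RGB-D rasters with spatially varying disk
    kernels, simulates focus-tunable (autofocal) and progressive lenses with
    realistic temporal dynamics driven by gaze-based control policies, and
    exercises them with a dynamic three-distance Landolt/Sloan matching task
    scored by a blur-dependent observer model. Includes synthetic RGB-D scene
    and gaze-trace generators, a generic gaze file format, and an experiment
    protocol runner with questionnaire loading and per-scene timestamped
    logging.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
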