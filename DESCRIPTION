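Package: needlenav
Title: Registration, Guidance Geometry and Monte-Carlo Accuracy Simulation
    for Augmented-Reality Needle Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational core of a fiducial-based augmented-reality
    needle-guidance system for transperineal prostate procedures.
    Provides rigid-body transforms between named coordinate spaces,
    least-squares point-to-point registration with the FLE/FRE/TRE
    error-budget calculus, physical models of the tracked patient and
    needle reference frames, deterministic planned-path and free-hand
    guidance state machines, and a seeded Monte-Carlo simulator that
    reproduces phantom accuracy experiments (image overlay error, visual
    needle-targeting error and needle-placement error) without any
    hardware, together with the accompanying statistical analysis plan.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
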