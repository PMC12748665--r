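Package: velflow
Title: Time-Varying Velocity-Field Modeling of Developmental Atlas Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a time-parameterized velocity field to corresponding point
    sets sampled at discrete developmental stages and integrates it to obtain
    diffeomorphic displacement fields between any two continuous timepoints.
    Provides physical-space raster containers with NIfTI input/output,
    multilevel weighted B-spline scattered-data approximation, fourth-order
    Runge-Kutta velocity-field integration, displacement-field inversion,
    weighted contour/region point sampling from label images, a log-scaled
    developmental time axis, synthesis of virtual templates at unsampled ages,
    and a synthetic-data generator with analytic ground-truth flows for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    Matrix,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
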