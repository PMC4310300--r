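Package: retinomap
Title: Activity-Dependent Development of the V1 Retinotopic Map
Version: 0.1.0
Authors@R: person("Retinomap", "Maintainers", email = "maintainers@retinomap.org",
                  role = c("aut", "cre"))
Description: Simulates the activity-dependent development of the primate
    primary visual cortex (V1) retinotopic map, in which eccentricity and
    meridional angle come to occupy roughly orthogonal cortical axes. Provides
    a boundary-constrained Kohonen self-organizing map (SOM) and a LISSOM
    (laterally interconnected synergetically self-organizing map) cortical
    sheet trained on rotated and dilated bar stimuli and probed with point
    inputs, together with the analytic complex-logarithmic retino-cortical
    transform used both as the cortical boundary constraint and as validation
    ground truth, stimulus synthesis (bars, rings, points, lesioned discs),
    map analysis (preference/selectivity, RMS error, angle histograms, lesion
    projection zone measurement), and a reproducible experiment runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
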