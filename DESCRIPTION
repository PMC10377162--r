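Package: tausense
Title: Fluorescence-Lifetime Nanosensor Analysis by TCSPC Reconvolution and
    Binding-Isotherm Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for fluorescence-lifetime
    (TCSPC, time-correlated single-photon counting) nanosensors based on
    molecularly imprinted polymer nanoparticles. Provides iterative
    reconvolution fitting of mono- and biexponential photon-counting decays
    against a measured instrument response function, extraction of the
    binding-responsive lifetime component, Hill and Langmuir binding-isotherm
    fitting across analyte titrations, and computation of sensor figures of
    merit (apparent dissociation constant, affinity constant, sensitivity,
    limit of detection, linear dynamic range). Includes a synthetic-data
    generator emulating photon-counting acquisition with Poisson noise,
    selectivity-panel and spiked-matrix workflows, and an end-to-end
    reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
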