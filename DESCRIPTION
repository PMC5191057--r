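Package: octenamel
Title: Quantitative Optical Coherence Tomography Assessment of Dental Enamel
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies dental enamel demineralization from stacks of
    optical coherence tomography (OCT) B-scan images. Implements averaged
    A-scan depth profiling with peak-index layer flattening and
    refractive-index depth scaling, enamel thickness estimation with
    percent reduction against a healthy reference, depth-binned total
    intensity fluctuation analysis over the visible 1 mm range, and
    intensity-threshold voxel volumetry of the enamel residual. Includes a
    synthetic layered tooth phantom generator with known ground truth
    (layer depths, lesions, multiplicative speckle) so every stage can be
    validated without clinical data, plus multi-page TIFF and raw-binary
    stack I/O and a reproducible comparative reporting workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
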