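Package: visalscene
Title: Saliency-Guided View- and Translation-Invariant Object Recognition in Cluttered Scenes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stream model of visual search and object identification in
    cluttered scenes. A dorsal-stream surrogate computes graph-based bottom-up
    saliency and fixates candidate objects; fixation-centred patches are passed
    through a Gabor V1 front-end into a four-layer hierarchical competitive
    network trained with a temporal-trace Hebbian rule, yielding combined view-
    and translation-invariant object representations. Performance is quantified
    with Shannon single-cell and population information measures and a Hebbian
    pattern-associator readout. Includes a procedural stimulus generator
    (objects renderable at arbitrary view angle, translation grids, cluttered
    test scenes with ground truth) and end-to-end evaluation drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    EBImage,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
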