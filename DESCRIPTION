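Package: nemadef
Title: Detection and Classification of Nematic Topological Defects in
    Confluent Cell Layers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies half-integer (+1/2 and -1/2) topological
    defects in the nematic orientation field of confluent cell layers from
    per-cell centroids and long-axis orientations, as produced by standard
    segmentation software. Builds a smoothed director field and scalar
    nematic order parameter on a fine grid, identifies candidate defect
    regions as contiguous low-order areas, crops 9x9 director regions of
    interest, and classifies them either by the boundary winding number or
    by a small convolutional neural network trained on labelled regions.
    Includes a seeded synthetic-tissue generator with planted defects for
    training and benchmarking, precision/sensitivity/F1 evaluation,
    defect-polarity estimation, and oriented ensemble averaging of velocity
    and director fields around detected defects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
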