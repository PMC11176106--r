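Package: corticount
Title: Quantification of Retrograde-Tracer Inputs to Layer 6 of Cat Primary
    Visual Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sampling-corrected quantification of retrogradely labeled neurons
    projecting to layer 6 of cat area 17: fraction of labeled neurons (FLN) per
    area and layer, laminar input profiles, 3-D Euclidean distances of labeled
    somata to injection-site centers, and kernel-density detection of periodic
    lateral clusters at the layer 3/4 border. Includes a synaptic-budget module
    that revises the Binzegger-style accounting of asymmetric synapses in layer
    6, with an inverse solver for the per-cell synapse counts hypothetical
    'layer 3/4 to layer 6' cell types would require, and a seeded synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
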