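Package: ketamap
Title: Ketamine-Evoked Disruption of Entorhinal and Hippocampal Spatial Coding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how sub-anesthetic ketamine disrupts
    spatial coding in the medial entorhinal cortex (MEC) and hippocampus.
    Converts spike trains, virtual-reality behavior traces, local field
    potentials and calcium-imaging event rasters into spatial-coding metrics
    (spatial information, trial-to-trial stability, crest factor, functional
    cell classes), cross-correlogram based monosynaptic connectivity with
    time-resolved transmission probability, unsupervised detection of the
    acute post-ketamine "decoherence" population state (UMAP embedding plus
    density clustering), trial-by-trial population similarity and remapping
    scores, baseline-trained position decoding with circular RMSE, and
    multitaper band-power time courses.  A synthetic-session generator with
    ground truth makes every stage testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    uwot,
    FNN,
    glmnet,
    Matrix,
    RSpectra,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
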