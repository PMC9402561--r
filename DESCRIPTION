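Package: qmribids
Title: Quantitative MRI File Collections: Validation, Simulation and Map Fitting
Version: 0.3.1
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for working with quantitative MRI (qMRI) datasets organized
    as entity-linked BIDS file collections. Provides a machine-readable schema
    registry of qMRI collection suffixes, linking entities, metadata
    requirements and map units; a filename parser and sidecar-JSON resolver
    implementing BIDS inheritance; a dataset validator that checks filename,
    collection and metadata level rules; pure forward signal models (spoiled
    gradient echo, inversion recovery, monoexponential decay, MP2RAGE,
    magnetization transfer, double-angle and actual-flip-angle B1+ mapping);
    voxelwise fitters that turn file collections into quantitative parameter
    maps (T1, T2, T2*, MTR, MTsat, B1+); a digital-phantom generator that
    emits valid synthetic qMRI raw datasets; and a derivatives writer that
    stores fitted maps with standardized units and full provenance.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
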