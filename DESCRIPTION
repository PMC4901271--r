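Package: neurorsa
Title: Spatio-Temporal Representational Similarity Analysis for MEG, fMRI
    and Layered Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Representational similarity analysis (RSA) across measurement
    spaces: time-resolved representational dissimilarity matrices (RDMs) from
    MEG sensor patterns via pairwise linear support-vector-machine decoding
    with trial sub-averaging, spatial RDMs from fMRI voxel patterns via
    Spearman correlation distance, and layer-resolved plus PCA-balanced
    summary RDMs from layered model activations.  Includes surface-based
    searchlight mapping with geodesic disks on triangulated cortical meshes,
    peak/onset latency extraction and layer-hierarchy statistics,
    nonparametric group inference (sign-permutation tests, cluster-extent
    correction, FDR, subject-pool bootstrap), occlusion-based receptive-field
    mapping for model units, and a deterministic synthetic-data generator
    that emulates multi-subject MEG/fMRI recordings with a controllable
    latency and regional hierarchy for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    png
Config/testthat/edition: 3
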