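Package: vascatlas
Title: Probabilistic Cerebral Artery Atlases and Automatic Artery Labeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds stereotactic probabilistic atlases of named cerebral
    arteries from cohorts of angiographic volumes and uses them for
    atlas-based automatic artery identification. Provides vessel
    segmentation (box smoothing and fractional-maximum thresholding),
    topology-preserving 3D skeletonization with branch-graph
    decomposition and pruning, label re-inflation, per-artery
    probability-map construction with alignment metrics (concatenated
    volume, arterial volume ratio, dominating volume, maximum
    probability), a rigid-body comparison atlas with volume-conserving
    re-binarization, leave-one-out validation with six-category outcome
    scoring, and a synthetic vascular phantom generator with known
    ground-truth labels and spatial transforms for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
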