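Package: cowpath
Title: Path-Finding Based Labeling of Circle of Willis Artery Centerlines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic labeling of the arterial centerlines of the circle
    of Willis from 3D time-of-flight magnetic resonance angiography. Provides
    NIfTI volume input/output with isotropic cubic resampling, Otsu
    thresholding and 3D seeded region growing, topology-preserving 3D
    skeletonization, conversion of skeletons to Euclidean-weighted voxel
    graphs, three path-finding methods (depth-first search, Dijkstra, A* with
    an admissible Euclidean heuristic) that connect manually annotated
    endpoint pairs into named vessel segments, evaluation statistics
    (per-segment correct/incorrect/undetected counts, accuracies, two-sided
    Fisher's exact tests) and a synthetic vascular phantom generator with
    ground-truth centerlines so that every stage is testable without imaging
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
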