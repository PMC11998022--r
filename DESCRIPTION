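Package: statemap
Title: Trajectory Inference and Cross-Trajectory Mapping for Cell-State
    Conversions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing single-cell trajectories of cell-state
    conversion experiments to each other and to an in-vivo reference.
    Implements diffusion-map embeddings with adaptive anisotropic kernels,
    absorbing-Markov-chain fate probabilities and differentiation
    potential, mutual-nearest-neighbour graph augmentation across
    timepoints and datasets, pseudotime binning with bin-to-bin
    multi-scale-distance mapping, clustering of smoothed gene-expression
    trends, and a metacell-level chromatin-accessibility stack (TF-IDF/SVD
    embedding, highly variable peaks, Kolmogorov-Smirnov differential
    accessibility, peak-dynamics classification, motif deviation scores
    with matched backgrounds, and region-set enrichment).  Seeded
    generators simulate branching conversion trajectories, an embryo-like
    bifurcating reference, and peak-accessibility experiments with known
    ground truth, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    mgcv,
    RSpectra,
    irlba,
    GenomicRanges,
    IRanges,
    S4Vectors,
    tibble,
    dplyr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
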