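Package: entroKNN
Title: Entropy-Guided Weighted k-Nearest-Neighbour Classification for
    Multi-Encoder Cell Image Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Adaptive k-nearest-neighbour classification of single-cell
    microscopy images represented by concatenated embeddings from several
    frozen image encoders. A Hierarchical Navigable Small World (HNSW)
    graph index supports approximate retrieval; the neighbourhood size k
    grows exponentially until the normalized Shannon entropy of neighbour
    labels falls below a threshold, and inverse-frequency class weights
    rebalance the neighbour vote under class imbalance. Also provides
    exhaustive encoder-subset selection by validation macro accuracy,
    representation-quality diagnostics (class cosine-similarity matrices,
    class separability, RBF centered kernel alignment, PCA intrinsic
    dimensionality, per-encoder loading contributions), cross-microscope
    magnification matching with CLAHE contrast normalization and
    mask-centered cropping, Otsu-based fluorescence-area quantification,
    and synthetic embedding and image generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
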