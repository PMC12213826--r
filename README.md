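# entroKNN

Entropy-guided, class-weighted, adaptive k-nearest-neighbour classification
of single-cell microscopy images from concatenated foundation-model
embeddings.

## The problem

Training a dedicated classifier for every new cell-imaging experiment is
expensive: labels are scarce, classes are heavily imbalanced (a typical
cell-death experiment yields thousands of living cells but only a few
hundred apoptotic ones), and a model tuned on one microscope transfers
poorly to another. An alternative is to keep several frozen, general-purpose
image encoders, concatenate their per-cell feature vectors, and classify by
retrieval: look up the labelled training cells nearest to a query embedding
and vote. `entroKNN` implements that retrieval classifier for
bioimage-analysis groups who already produce per-cell embeddings and want a
trainable-in-seconds, auditable classifier with a built-in confidence
readout.

## The method

Given a labelled database of N concatenated embeddings with C classes
(N_i samples in class i), the classifier:

1. builds a Hierarchical Navigable Small World (HNSW) graph index over the
   raw concatenated vectors (no normalization or dimensionality reduction);
   the Canberra metric Σ_d |a_d − b_d| / (|a_d| + |b_d|) uses an exact flat
   scan,
2. freezes inverse-frequency class weights once at build time:
   **w_i = N / (C · N_i)**, so minority classes vote with more weight,
3. for each query grows the neighbourhood from k_min, doubling k until the
   normalized entropy of the k neighbour labels
   **H_norm = − Σ_i p_i ln p_i / ln k** falls strictly below a threshold or
   k_max is reached,
4. predicts **y_pred = argmax_l Σ_j w_{y_j} · 1{y_j = l}** over the final
   neighbour set, and reports **certainty = (1 − H_norm) × 100 %**.

Around the classifier the package provides exhaustive encoder-subset
selection by validation macro accuracy (all 2^n − 1 subsets),
representation diagnostics (class cosine-similarity matrices after PCA,
class separability, RBF centered kernel alignment, PCA intrinsic
dimensionality, per-encoder loading contributions), cross-microscope
preprocessing (µm/px geometry, magnification rescaling, CLAHE, grayscale,
mask-centered 224×224 crops), Otsu-based fluorescence-area quantification,
and synthetic embedding/image generators so the whole pipeline is testable
without any external data.

## Worked example

```r
library(entroKNN)

# a 4-class imbalanced mixture observed through two encoders, one of which
# is informative; 90/9/1 stratified splits
cfg <- syntheticEmbeddingConfig(
  classNames = c("living", "necrotic", "dead", "apoptotic"),
  perClassCounts = c(461, 137, 73, 71),
  blockDims = c(encA = 16, encB = 8), informativeBlocks = "encA",
  classSeparation = 6, seed = 1
)
es  <- generateEmbeddingSet(cfg)
idx <- buildIndex(es, config = searchConfig(kMin = 3, kMax = 48,
                                            entropyThreshold = 0.3))
val <- splitSet(es, "val")
head(adaptivePredict(idx, val), 3)
#>      row_id predicted_label k_used entropy certainty_percent
#> 1 cell00016          living      3       0               100
#> 2 cell00031       apoptotic      3       0               100
#> 3 cell00035        necrotic      3       0               100
macroAccuracy(labels(val), adaptivePredict(idx, val)$predicted_label)
#> [1] 100
```

Each prediction row reports the class label, the neighbourhood size the
entropy-guided search settled on (`k_used` = 3 means the very first
neighbourhood was already pure), the normalized entropy and the certainty
percentage. On this well-separated fixture every validation query stops at
`kMin` with a pure neighbourhood, giving 100 % macro accuracy (the
unweighted mean of per-class recalls).

Encoder-subset selection and the shipped incumbent presets:

```r
sel <- selectBestSubset(splitSet(es, "train"), val,
                        searchConfig(kMin = 3, kMax = 20))
sel$subset
#> [1] "encA" "encB"   # the winner contains the informative encoder
ewcPresets("cell-death-nanolive")$config
#> SearchConfig: k in [3, 100], entropy threshold 0.6, metric Canberra, growth x2
```

A command-line interface wraps the same functions
(`inst/cli/entroknn simulate|build|predict|select|analyze|preprocess`).

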