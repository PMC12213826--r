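---
title: "Entropy-guided weighted k-NN over multi-encoder cell embeddings: model and design notes"
author: "entroKNN authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-guided weighted k-NN: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entroKNN)
```

## The model

`entroKNN` classifies cell images by retrieval in a concatenated embedding
space. Several frozen image encoders each map a cell image to a feature
vector; the vectors are juxtaposed column-wise, untouched — no L2
normalization, centering or dimensionality reduction — because raw features
preserved validation accuracy in the regime this method targets, and any
per-block rescaling would silently reweight encoders relative to one
another. The labelled training matrix backs an approximate nearest-neighbour
index; classification is a class-weighted vote among retrieved neighbours.

Three mechanisms carry the method:

**Inverse-frequency class weights.** With N database rows over C classes,
class i holding N_i rows, the vote weight of class i is
`w_i = N / (C * N_i)`. The weights satisfy `sum_i w_i * N_i = N` (each class
contributes equally in aggregate) and are frozen when the database is built,
never recomputed per query, so predictions are a pure function of the index.
With reweighting disabled all weights are 1 and the vote reduces to
plurality.

**Normalized neighbourhood entropy.** For the k retrieved labels with
empirical class frequencies p_i,
`H_norm = -sum_i p_i ln(p_i) / ln(k)` (with `0 ln 0 := 0`, summing over
observed classes). Division by `ln k` keeps the value in [0, 1] for every k:
0 for a pure neighbourhood, 1 only when all k labels are distinct. Note the
consequence for few-class problems: an even 6/6 split of two classes at
k = 12 gives `ln 2 / ln 12 ≈ 0.28`, not 1 — the normalizer is the number of
neighbours, not the number of classes. Entropy is always computed from raw
label counts, not reweighted ones, so the uncertainty readout is independent
of the vote rebalancing.

**Adaptive neighbourhood growth.** k starts at `kMin` and is multiplied by
`growthFactor` (default 2, the final step clamped to `kMax`) until
`H_norm` falls strictly below the configured threshold or `kMax` is
reached; the prediction and the reported entropy come from the last
retrieved neighbour set. Doubling is used because each extra step roughly
doubles per-query runtime, making the schedule's cost geometric; `kMin >= 2`
is enforced because `ln 1 = 0` makes the entropy undefined at k = 1. The
certainty readout is `(1 - H_norm) * 100`, a strictly decreasing function
of the entropy.

## Retrieval backends

The L2 metric uses a Hierarchical Navigable Small World graph implemented
in C++ (`src/hnsw.cpp`): layered proximity graphs with geometric level
assignment (`mL = 1 / ln M`), beam-search insertion (`efConstruction`) and
beam-search queries (`efSearch`). Defaults are M = 32,
`efConstruction = 200`, and `efSearch = max(2k, 128)` — the query beam
grows with k so recall does not collapse when the adaptive search reaches
large neighbourhoods. The graph is rebuilt deterministically from the
stored matrix and seed after deserialization (external pointers do not
survive `saveRDS`).

The Canberra metric `sum_d |a_d - b_d| / (|a_d| + |b_d|)` (terms with zero
denominator contribute 0) uses an exact flat scan instead: proximity-graph
heuristics are not well behaved for strongly non-Euclidean dissimilarities,
and the behavioural contract of the index is metric-correct retrieval, not
a particular data structure. The test suite holds both backends to equality
with independent brute-force scans on instances up to 500 points.

Weighted-vote ties are broken by the smaller summed neighbour distance
among the tied classes, then lexicographically — deterministic and
distance-aware without letting distances into the vote itself.

## Encoder-subset selection

`selectBestSubset()` evaluates every non-empty subset of the registered
encoders (2^n − 1, guarded at n ≤ 12) with a fixed search configuration:
build the index on the training split, score macro accuracy on the
validation split, return the argmax (the *incumbent*) with a full
leaderboard. Macro accuracy — the unweighted mean of per-class recalls —
is the selection target because it is insensitive to the class imbalance
the weighting mechanism exists to counter. Ties prefer fewer encoders,
then enumeration order. Search parameters (k bounds, threshold, metric)
are held fixed during the sweep rather than re-tuned per subset; the sweep
is embarrassingly parallel and order-independent, and per-subset
hyperparameter grids can be layered on top by the caller. Shipped presets
(`ewcPresets()`) record the incumbent configurations of the imaging
regimes the method was developed on, plus a recommended fallback
combination for unseen data.

## Representation diagnostics

* `classCosineMatrix()` projects embeddings with centered PCA (to 100
  dimensions by default, reduced with a warning on smaller inputs) and
  averages cosine similarities per class pair. Diagonal cells exclude
  self-pairs, which are identically 1 and would inflate intra-class means.
  Because PCA centers the data, two perfectly orthogonal pure clusters map
  to opposite points and score −1 off-diagonal, not 0; interpretation of
  the matrix should always be relative, not absolute.
* `separability()` reports mean diagonal (intra-class), mean off-diagonal
  (inter-class), and the per-class diagonal-minus-row-sum average.
* `rbfCKA()` uses Gaussian kernels with the median-heuristic bandwidth and
  the biased HSIC estimator `tr(KHLH)/(n-1)^2` — valid from n = 3 and, with
  the median heuristic, invariant to rotation and isotropic scaling of
  either representation.
* `intrinsicDimensionality()` counts components to 95% cumulative explained
  variance; `blockContributions()` scores each encoder block by its mean
  squared loading (energy — squares avoid sign cancellation) over the top
  components (default: the intrinsic dimensionality), normalized to sum
  to 1.
* PCA components are sign-fixed (largest-magnitude loading positive) so all
  diagnostics are deterministic across linear-algebra backends.

## Imaging preprocessing

Cross-device transfer first matches magnification: µm/px = field of view /
pixels per axis, and the rescale factor is source divided by destination
pixel size (0.19/0.322 ≈ 0.59 for the 60×-to-20× transfer the defaults
describe), applied with bilinear interpolation. CLAHE (clip limit 2, 8×8
tiles by default) normalizes contrast; inputs whose dimensions are not
tile-divisible are edge-padded and cropped back, and constant images are
returned unchanged (there is no contrast to equalize — the underlying
equalizer would otherwise rescale them arbitrarily). CLAHE is not strictly
idempotent; the tests freeze an empirically measured double-application
band rather than pretending it is. Grayscale conversion uses ITU-R 601
luminance weights. Crops are 224×224 with the center at zero-based index
112, zero-padded at borders with the padded fraction recorded so heavily
padded crops can be filtered downstream (a corner-centered crop is exactly
75% padding).

Fluorescence quantification thresholds each frame with the canonical Otsu
criterion — the gray level maximizing between-class variance
`w0 w1 (mu0 - mu1)^2` over the integer histogram, computed in a vectorized
cumulative form with all moments in double precision — then labels the
8-connected components of the above-threshold mask and sums their areas.
The threshold is defined to *attain* the exhaustive maximum; when several
thresholds tie exactly, the smallest is returned.

## The synthetic data generator

`generateEmbeddingSet()` emulates the statistical regime the classifier
assumes: per-encoder blocks of differing dimensionality, informative blocks
drawing each class from an isotropic Gaussian whose means sit at
`separation * noiseScale / sqrt(2)` times the first C coordinate axes (so
every pairwise mean distance equals `separation * noiseScale` — one
difficulty dial), non-informative blocks identically distributed across
classes, class imbalance via per-class counts (the default 461/137/73/71
mirrors a published cell-death skew at one tenth scale), 90/9/1
train/val/test splits stratified per class by largest-remainder allocation
whose split totals match the rounded global fractions, and an affine
domain shift (`gain_d = exp(0.1 m g_d)`, `offset_d = m sd_d z_d`) standing
in for a second microscope — the simplest transform that moves and
rescales the cloud while preserving neighbourhood topology and labels.

What the generator deliberately does not model: the actual encoders'
feature statistics (correlated, heavy-tailed, anisotropic), label noise,
batch effects within one device, or photorealistic cell appearance
(`generateCellImage()` renders anti-aliased disks with Gaussian noise,
enough to exercise thresholding, cropping and contrast code). Passing
tests therefore demonstrate that the machinery is correct under its own
assumptions — pure-noise blocks are rejected by subset search, reweighting
protects minority recall, retrieval matches brute force — not that any
particular accuracy will be reached on real microscope data.

## Problem sizes and numerical choices

The test and acceptance workloads use desk-scale instances: databases of a
few hundred to ~750 rows, 8–24 feature dimensions, 5 seeds for
stochastic claims, 50 random images for threshold checks — sizes at which
exact brute-force oracles are computable so every approximate component
can be held to exact-equivalence contracts. Degenerate inputs error
explicitly (empty databases, non-finite rows, k < 2 for entropy, constant
images for Otsu, singleton classes for within-class similarity,
zero-variance inputs for CKA); `kMax` beyond the database size clamps with
a warning rather than erroring, since it is a configuration default
meeting a small database, not a user mistake.

## Known limitations

* Entropy-guided stopping interacts with class count: with few classes the
  `ln k` normalizer shrinks H_norm as k grows, so very mixed neighbourhoods
  can slip under lenient thresholds at large k.
* The HNSW graph is rebuilt (deterministically) on load rather than
  serialized; for very large databases persisting the graph itself would be
  preferable.
* Distance-weighted voting, soft-probability calibration and online
  insertion are out of scope; the vote uses class weights only.
* Subset search is exhaustive by design and guarded at 12 encoders.
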