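---
title: "dbpWET: methods, assumptions and parameter choices"
author: "dbpWET maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dbpWET: methods, assumptions and parameter choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbpWET)
```

# Overview

`dbpWET` predicts whether a protein binds DNA from its primary sequence
alone. The model treats a protein as a sentence of overlapping k-mer
"words", learns three unsupervised word-embedding representations of
those words, fuses the three per-protein feature blocks with weights
learned by differential evolution, selects the most informative fused
features by Shapley-value importance, and classifies with a
one-dimensional convolutional network. This vignette explains each
stage, the assumptions behind it, and why the defaults are what they
are.

# Sequence preparation

Sequences shorter than 50 residues are dropped, as are sequences
containing non-standard residues (anything outside the 20-letter amino
acid alphabet, e.g. `X`). The rationale: very short chains rarely form
the structured binding domains the model is implicitly looking for, and
ambiguous residues would either need imputation or would silently create
out-of-vocabulary tokens. `filterSequences()` reports what it dropped
and why.

Each surviving sequence is tokenised into overlapping k-mers
(`tokenizeSequence`, default k = 3, stride 1). Tripeptides are a common
sweet spot: the vocabulary (≤ 20³ = 8000 types) is small enough to
estimate embeddings from a modest corpus, yet long enough to capture
local physicochemical context.

# The three encoders

All three encoders produce one vector per k-mer type; a protein's
feature vector is the average of its token vectors (`embedSequence`).
Averaging makes the representation length-invariant, at the cost of
word-order information — which is partly recovered later by the
convolutional classifier operating on the fused feature axis.

**CBOW** (`trainCBOW`) predicts a centre token from the average of its
context vectors within a symmetric window (default 5). For small
vocabularies the loss is the exact full softmax; above
`maxSoftmaxVocab` (default 2000) the normalisation term becomes the
bottleneck, so training switches to negative sampling with a
unigram^0.75 noise distribution — the standard word2vec estimator of the
same objective. The cap is a pure compute trade-off: at |V| ≈ 2000 the
full softmax is still a few milliseconds per position, beyond that it
dominates the run time with no accuracy benefit on our corpus sizes.

**GloVe** (`trainGlove`) factorises the log of the global co-occurrence
matrix, minimising the weighted least-squares loss
\(\sum f(X_{ij})(w_i^\top \tilde w_j + b_i + \tilde b_j - \log X_{ij})^2\)
with the usual weighting \(f(x) = \min(1, (x/x_{max})^{3/4})\). We use
full-batch gradient descent rather than AdaGrad over shuffled pairs:
protein corpora at this scale have at most a few hundred thousand
non-zero pairs, so full-batch steps are cheap, deterministic given the
seed, and give a monotone loss trace that the test suite can assert on.

**fastText** (`trainFastText`) is a skip-gram model with negative
sampling in which every k-mer vector is the sum of its character n-gram
vectors (default n ∈ [1, 2]). Because tripeptides share their
constituent residues and dipeptides, subword sharing both regularises
rare k-mers and lets the model embed k-mers never seen in training — the
out-of-vocabulary path in `embedSequence` composes them on the fly.

# Differential-evolution fusion

The three blocks are concatenated after scaling block *i* by a weight
\(w_i \in [0,1]\). The weights are learned by classic DE/rand/1/bin
(`deOptimize`): population 20, mutation factor F = 0.5, crossover rate
CR = 0.5, box constraints enforced by reflection, greedy selection with
ties going to the trial vector. The fitness of a weight vector is
1 − (stratified k-fold CV AUC) of a ridge probe on the weighted
concatenation. A ridge classifier — not the CNN — is the probe because
the fitness is evaluated thousands of times; with per-fold Gram matrices
precomputed per block, one evaluation costs milliseconds and the
optimum correlates well with downstream CNN performance. DE rather than
a gradient method because the CV-AUC objective is piecewise constant in
the weights (AUC only changes when score orderings flip), hence
gradient-free optimisation is the natural choice.

# Shapley-value feature selection

Fused features are ranked by mean absolute Shapley value over the
training instances (`rankFeatures`). Three estimators are provided:

- `exactShapley` enumerates all coalitions (capped at 15 features) and
  satisfies efficiency, symmetry and the dummy axiom to machine
  precision — it exists mainly as the oracle the other estimators are
  tested against;
- `sampledShapley` averages marginal contributions over random
  permutations (seeded, so deterministic);
- for full-width matrices (hundreds of features) a gradient-boosted
  tree surrogate (xgboost) is fitted to the labels and scored with
  interventional TreeSHAP, which is exact for the surrogate and fast.

Ranking once on the full training set and then cross-validating the
top-k subsets mildly leaks selection information into the CV estimate;
`strictCV = TRUE` in `pipelineConfig()` instead re-ranks inside every
training fold. The default is the faster variant because the final
*model comparison* across k values uses the same protocol for every k,
so the ranking bias cancels when choosing k — but the strict estimate is
the one to report as an unbiased performance figure.

The candidate sizes come from `selectionGrid()`: 200 to 450 in steps of
50, truncated to the fused width. With three 200-dimensional blocks the
fused width is 600, so the grid spans one-third to three-quarters of the
features.

# The CNN classifier

`buildCNN`/`trainCNN` implement a 1-D CNN over the selected feature
vector: up to three convolution blocks (filters 32/48/64, kernel sizes
3/4/5, stride 1), each followed by batch normalisation, ReLU and
width-2 max pooling, then a dense hidden layer with dropout and a
sigmoid output trained with Adam on binary cross-entropy. Early stopping
monitors a validation split when `valFraction > 0`.

The ablation variants studied with `ablateConfig` are: reduced stack
capacity filters (RSCF, half-width filters), varied pooling scheme (VPS,
average pooling), varied kernel sizes (VKS, uniform kernels), and
removed fully-connected layer (RFCL).

The per-batch forward/backward pass is compiled C++
(`src/cnn_ops.cpp`, RcppArmadillo). A complete pure-R implementation of
every layer (im2col convolution, batch norm, pooling, dropout, dense)
remains in the package as the reference: the test suite checks C++
against R to ~1e-12 on probabilities and all gradients, and checks the
gradients against central finite differences. Dropout masks are drawn
from R's RNG inside the C++ code in the same order as the R reference,
so the two paths are numerically interchangeable and all results are
reproducible from the single pipeline seed.

Learning-rate note: the package default of `1e-5`-scale training
schedules in the literature assumes datasets of tens of thousands of
sequences. On the corpus sizes the synthetic benchmark uses (hundreds of
sequences, tens of epochs), `1e-3` with Adam reaches the same loss in
two orders of magnitude fewer epochs; `demoPipelineConfig()` encodes
that scaling (and more encoder epochs, since small corpora need more
passes per token type) without changing any architectural choice.

# Evaluation

`classMetrics` computes accuracy, sensitivity, specificity, precision,
F1 and MCC directly from the confusion counts; zero denominators yield
`NaN` with a warning rather than silent zeros. `rocAUC` integrates the
empirical ROC by trapezoids with proper tie handling (equivalent to the
Mann–Whitney statistic). `crossValidate` uses stratified folds (class
proportions preserved to within one sequence per fold) and reports both
per-fold metrics and the pooled out-of-fold metrics; the pooled AUC is
the headline number because per-fold AUCs on small folds are noisy.
`independentTest` refuses any id overlap between training and test sets,
and `runPipeline` embeds the test set with the training-fitted encoders
only, so no test information reaches the encoders, the fusion weights or
the feature ranking.

# The synthetic benchmark

`simulateProteins` draws background sequences from a fixed amino-acid
composition (approximating natural protein composition) with lengths
uniform in a range, then plants short DNA-binding-like motifs into the
positive class at Poisson-distributed counts (rate scaled by
`effectSize`) and uniform offsets, recording every planted motif and
offset in a manifest attribute. This gives a benchmark whose signal is
known by construction: `effectSize = 0` produces an undetectable
difference (AUC ≈ 0.5 is the correct answer), larger values produce
k-mer composition differences that a sound pipeline must detect.

Its realism limits are worth stating: real DNA-binding determinants
include structural context, charge patches and disorder, none of which a
motif-planting generator reproduces; sequence lengths here are much
shorter than typical transcription factors; and background composition
is i.i.d., whereas real proteins have local composition structure. The
generator validates the pipeline's machinery, not its biological
performance.

`deFitnessFixture` is the analogous fixture for the fusion stage: three
Gaussian feature blocks in which only the first carries class signal, so
a correct DE run must drive the first weight above the others.

# Reproducibility

Every stochastic stage takes a seed derived from the single pipeline
seed via `deriveSeed(seed, stageName)` (a deterministic hash), and
`withSeed` scopes all RNG use so that library calls do not perturb the
global RNG stream. Two `runPipeline` calls with the same data, config
and seed produce bit-identical models and reports.

# Session info

```{r}
sessionInfo()
```
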