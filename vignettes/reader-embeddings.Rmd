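---
title: "Classifying multi-annotator chest radiographs with reader embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying multi-annotator chest radiographs with reader embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Epidemiological studies that rely on chest-radiograph (CXR) interpretation —
pneumonia burden estimation, vaccine-impact trials — suffer from inter-reader
and intra-reader variability. Under the WHO standardized methodology a
paediatric CXR is assigned to one of five categories (consolidation, other
infiltrate, both, normal, uninterpretable), and multi-site panels routinely
show readers with very different sensitivity/specificity profiles. The usual
remedy is adjudication: two initial readers per site, random arbitrator pairs
on disagreement, consensus discussion on persistent disagreement — and then a
model is trained on the arbitrated *final* label, discarding the individual
reads.

`readernet` implements and tests the alternative: train a single
convolutional classifier that *conditions on reader identity* — predicting how
each reader would classify the image — and aggregate the per-reader
predictions at inference time with an unweighted mean. Training on individual
(noisier) labels preserves signal that the arbitration process averages away,
and aggregating per-reader predictions behaves like an ensemble whose members
share one set of convolutional weights.

## The model

The backbone ends with global average pooling (GAP), so its final feature map
becomes a D-dimensional image embedding $h(x)$. The reader branch maps reader
$r$ through an $R \times 32$ embedding table, an affine projection to
dimension D, and an activation $\sigma$ (identity, ReLU, tanh, or sigmoid):

$$ m_r = \sigma(W\,e_r + b), \qquad
   p(\cdot \mid x, r) = \operatorname{softmax}(V^\top (h(x) \odot m_r) + c). $$

The element-wise product $\odot$ lets each reader re-weight every image
feature. With all-ones modulation ($m_r = \mathbf 1$) the model reduces
exactly to the no-embedding baseline — we initialize near this point
(projection bias 1, table rows $\mathcal N(0, 0.01^2)$) so training starts
from baseline behaviour. With nonnegative activations (ReLU, sigmoid) the
*direction* of a feature's association with a class cannot flip between
readers; identity and tanh allow sign flips. The reader branch adds
$R \cdot 32 + 32 D + D$ parameters.

At inference the model produces one probability vector per reader; the final
prediction is the unweighted column mean with argmax ties broken toward the
lowest canonical class index. All readers known to the model are aggregated,
including readers who never annotated the image.

The trainable backbone in this package is a compact three-block CNN
(3×3 conv → ReLU → 2×2 max-pool, channel widths 8/16/D, D = 32 by default)
operating on single-channel images at 64×64 — sized so that the full
two-variant experiment runs on one desktop CPU core in minutes. The residual
backbones of full-scale radiograph work (at 3×224×224 with the standard
resize-to-300/crop-to-224 augmentation pipeline, which the package also
implements) are accepted in the model specification but not trainable here;
they would require a GPU deep-learning runtime.

## Training

* One occurrence of each training image per epoch, so both variants make the
  same number of weight updates: the reader-label variant samples one of the
  image's reader annotations uniformly per epoch (initial, arbitration and QC
  reads; consensus records are attributed to a reader pair, not a single
  reader, and are excluded from the per-reader pool), while the final-label
  variant trains on the arbitrated final label.
* Cross-entropy loss (mean over the batch); per-group learning rates and
  weight decays (convolutional layers, classifier head, reader projection,
  embedding table); an optional max-L2-norm projection of embedding rows
  after every optimizer step (the embedding table's only regularizer). The
  optimizer is Adam by default: training the compact backbone from scratch
  with momentum SGD proved highly sensitive to the interaction of seed and
  learning rate at desk scale (terminal accuracies varied by tens of points
  across seeds at any fixed rate we tried), whereas Adam's per-parameter
  scaling converges reliably; momentum SGD remains available in the
  configuration.
* Learning-rate schedule: halving after fixed milestone epochs. The
  full-scale schedule (150 epochs, halving at 50 and 100) is the default of
  `lr_at_epoch()`; the desk experiment uses 30 epochs with halving at 15 and
  25, which is the same shape at desk scale and removes the end-of-training
  fluctuation a constant rate leaves behind.
* Per-epoch validation mirrors the training target of each variant: the
  baseline is scored against the arbitrated final labels, while the
  reader-label variant predicts conditionally on one uniformly sampled
  annotating reader per validation image and is scored against *that
  reader's own annotation*. This is why the reader-label model shows lower
  validation accuracy and higher validation loss during training — its
  objective is noisy individual behaviour, capped by reader self-consistency
  — while its *aggregated* test accuracy is comparable or better: the
  aggregate averages the annotation noise out.
* The two variants have different optimization sweet spots (their optimal
  learning rates differ by an order of magnitude in full-scale tuning runs),
  so the experiment configuration supports per-variant training overrides;
  the defaults give the reader-label variant a hotter embedding-table rate.

## Hyper-parameter search

`run_halving()` implements synchronous successive halving over a random
search space (log-uniform learning rates and weight decays, uniform dropout
and augmentation proportions, categorical batch size, activation, max-norm).
All sampled configurations are trained to the first rung; the top `1/eta` by
validation accuracy are promoted to each subsequent rung; survivors of the
last rung are trained to the full budget. The asynchronous variant of this
scheme is an efficiency device for clusters and does not change the selection
rule in expectation, so the synchronous form is preferred here for exact
reproducibility and exact epoch accounting. The full-scale preset (300
samples, rungs 10/20/40/80, 150-epoch budget) is available as configuration;
tests and the desk profile use 16 samples with rungs 2/4/8 and a 12-epoch
budget.

## The synthetic panel

No public multi-reader paediatric CXR dataset exists at desk scale, so the
package ships a generator that emulates the *statistical structure* of a
multi-site reading study:

* **Images.** Grayscale 64×64 renders with two darker elliptical lung fields
  on a brighter thorax: consolidation adds one dense bright blob (the
  generator keeps the blob mask, which doubles as a ground-truth region of
  interest for Grad-CAM checks); other-infiltrate adds diffuse patchy
  texture; both adds both; uninterpretable applies heavy blur, contrast
  compression and occluding bands. Class prevalence defaults to
  15/24/11/40/10% and sites differ in their share of normal images.
* **Readers.** Each reader is a 5×5 row-stochastic confusion matrix. Base
  off-diagonal mass follows a fixed clinical confusability pattern, plus a
  strong reader-specific *bias class* receiving most of each reader's error
  mass — readers in multi-site studies disagree systematically, not just
  randomly (initial-reader concordance in the motivating study was only
  44%). Initial-reader diagonal accuracy spans 0.55–0.90 across sites.
  The two readers of a site are matched in marginal accuracy (`pair_gap = 0`)
  and differ in bias class: this makes within-pair dissimilarity purely
  systematic, which is the property that renders reader identity
  *identifiable* from conditional predictions. (With an accuracy gap inside
  the pair, even the data-generating confusion rows fail a paired
  self-agreement comparison on desk-scale test sets — the accuracy difference
  confounds the likelihood comparison — so matched pairs are the
  well-posed design.)
* **Age effect.** Reader agreement improves with child age: off-diagonal
  mass is scaled by `max(0.3, 1 − age·slope/120)` (age in months) and
  renormalized. The functional form is a free design choice; only
  monotonicity and a floor are essential.
* **Arbitration.** Two initial site readers; on disagreement two distinct
  arbitrators chosen uniformly at random; on persistent disagreement the
  consensus discussion — a human process with no published mechanism — is
  simulated as a single draw from the average of the two chosen arbitrators'
  age-adjusted rows. 10% of initially concordant images receive a QC re-read
  by one arbitrator that never changes the final label but enters the
  training pool as an ordinary reader annotation.

What the generator does **not** emulate: anatomy, acquisition physics,
film-digitization artefacts, reader drift over time (intra-reader
variability), or correlated errors between readers viewing the same ambiguous
finding. Passing tests on this generator therefore demonstrate that the
machinery — conditional modelling, aggregation, arbitration handling —
behaves as designed under controlled reader noise; they do not certify
performance on real radiographs.

## Numerical and design choices

* Canonical class order (consolidation, other infiltrate, both, normal,
  uninterpretable) fixes confusion-matrix axes, softmax output order and
  argmax tie-breaking everywhere.
* Probabilities, not logits, are averaged at aggregation; softmax outputs are
  the model's predictions.
* One-vs-rest AUC uses the midrank tie convention
  (`P(pos > neg) + 0.5 P(tie)`); classes lacking positives or negatives are
  reported `NA` and excluded from the unweighted mean with a warning.
* Grad-CAM: channel weights are the spatial mean of the target-logit gradient
  at the final conv activations; the rectified weighted sum is bilinearly
  upsampled and max-normalized per image (an all-zero map stays zero).
* Dropout sits at a single site, on the (modulated) pre-classifier embedding.
* All randomness derives from named per-stage substreams of one root seed;
  per-image substreams make simulation reproducible independent of
  generation order. Single-threaded execution is bit-reproducible.
* Convolution/pooling forward and backward passes are implemented as
  im2col + GEMM kernels in C++ (RcppArmadillo); gradients are verified
  against finite differences in the test suite.

## Problem sizes

The reference desk experiment — the configuration of
`default_experiment_config()` and `scripts/acceptance.R` — simulates 1,500
images (≈1,442 patients, ~4% with a second image) at 64×64 with 6 initial
readers and 2 arbitrators, holds out 20% of patients, and trains both
variants for 30 epochs at batch size 16. Property tests run on much smaller
panels (tens of images at 32×32, a few epochs). The full-scale configuration
(4,172 images of 4,008 patients, 18 readers, 150 epochs, 300-sample ASHA) is
expressible in the same configs but is not exercised by the tests.

## Known limitations

* The toy backbone saturates the synthetic task; absolute accuracies are far
  above what real radiographs yield, so only *relative* statements (baseline
  vs reader-embedding, curves, localization) are meaningful.
* Grad-CAM localization depends on the optimization path: across repeated
  training runs an occasional model classifies consolidation through
  features whose positive evidence is not spatially confined to the blob,
  and its heatmaps then fail to localize even when the classification is
  correct — a known behaviour of gradient-based saliency, not a defect of
  the map computation.
* Aggregation weights are uniform; learning per-reader weights (stacking) is
  deliberately out of scope.
* Residual backbones and DICOM ingestion are not implemented.
* The consensus surrogate (averaged confusion rows) is the simplest faithful
  stochastic model of a discussion; richer models (weighted by seniority,
  anchoring on the first arbitrator) would change arbitration statistics.
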