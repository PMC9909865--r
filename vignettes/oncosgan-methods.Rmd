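---
title: "Semi-supervised adversarial classification of somatic variants: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised adversarial classification of somatic variants: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clinical laboratories accumulate somatic variants far faster than experts can
label them as oncogenic (driver) or benign (passenger).  Labeled sets number
in the thousands; candidate pools from public knowledgebases number in the
millions.  `oncosgan` implements a semi-supervised generative adversarial
network (SGAN) that learns a benign/oncogenic classifier from a small labeled
table of per-variant annotation features while exploiting a large unlabeled
pool drawn from the same feature distribution.

Each variant is described by 35 raw features: 12 discrete clinical
evidence scores in $\{-1, 0, 1, 2\}$ (the AMP/ASCO/CAP 2017 evidence tiers,
as emitted by automated evidence-collection tools) and 23 continuous
deleteriousness scores from third-party functional predictors.  Computing
these annotations from raw variant calls is out of scope; the package
consumes the tabulated scores.

## Model

**Discriminator.**  A three-stage 1-d convolutional network (kernel 3,
stride 2, leaky-ReLU activations) runs over the encoded 71-dimensional
feature vector as a single-channel signal; the flattened penultimate
activations feed a linear head with two logits $l_1$ (benign) and $l_2$
(oncogenic).  Class probabilities are the softmax
$p(y{=}i \mid x) = e^{l_i} / (e^{l_1} + e^{l_2})$, and the *interpretation
score* of a variant is $p(y{=}\text{oncogenic} \mid x) \in [0, 1]$.

The same two logits answer a second question.  Writing
$Z(x) = e^{l_1} + e^{l_2}$, the probability that an input is real rather
than generated is
$$D(x) = \frac{Z(x)}{Z(x) + 1},$$
which is exactly $1 - p(\text{synthetic})$ of the 3-class softmax obtained
by appending a third logit pinned at $0$: no extra output unit is needed.
Both quantities are computed through log-sum-exp
($\log D = \mathrm{lse}(l_1,l_2) - \mathrm{lse}(l_1,l_2,0)$), so extreme
logits neither overflow nor lose the gradient.

**Losses.**  The discriminator minimizes
$L = L_{\text{sup}} + L_{\text{unsup}}$ with
$$L_{\text{sup}} = -\,\mathbb{E}_{x,y}\, \log p(y \mid x), \qquad
  L_{\text{unsup}} = -\left\{ \mathbb{E}_{x}\, \log D(x)
  + \mathbb{E}_{z}\, \log\bigl(1 - D(G(z))\bigr) \right\}.$$
The generator — four linear layers with batch normalization, leaky-ReLU,
dropout 0.6 and a tanh output affinely mapped into $[0,1]$ to match the
min–max-scaled features — minimizes the feature-matching loss
$$\bigl\lVert \mathbb{E}_x\, f(x) - \mathbb{E}_z\, f(G(z)) \bigr\rVert_2^2,$$
where $f(\cdot)$ denotes the discriminator's penultimate-layer activations.
The formulation of the adversarial objective is sometimes written with
$D(\cdot)$ in this norm; we follow the feature-matching definition on
intermediate activations, which is the behaviour that stabilizes
semi-supervised GAN training, and expose `feature_source = "logits"` in
`discriminator_spec()` as the alternative reading.

**Training.**  Each minibatch cycle uses 500 labeled, 500 unlabeled and 500
generated variants; the discriminator is updated first, then the generator,
with fresh Gaussian noise for each step.  Adam (initial learning rate
0.0095, moments 0.9/0.999) optimizes the two networks separately.  Because
labeled pools are class-imbalanced (about 1:3 oncogenic:benign), labeled
minibatches are re-drawn every cycle with equal class probability, with
replacement.  One *epoch* is one pass of
$\lceil n_{\text{unlabeled}} / 500 \rceil$ cycles over the shuffled
unlabeled pool — the mixed-pool setting needs a convention and this is
ours.  There is no early stopping; validation metrics can be logged per
epoch when a held-out table is supplied.

## Feature pipeline

1.  **Missingness filter**: variants with more than 13 of 35 raw values
    missing are removed.
2.  **Imputation**: every remaining missing entry is the mean of that
    column over its $k = 40$ nearest neighbours.  Distances are Euclidean
    over mutually observed coordinates, rescaled by
    $\sqrt{35 / |\text{observed}|}$ (the nan-Euclidean convention); only
    rows observing the target column can donate; ties break by row order
    for reproducibility.  The imputer's neighbour reference is the union of
    labeled and unlabeled *training* rows — test variants are imputed
    against that reference, never against each other.
3.  **Evidence encoding**: each discrete score becomes a 4-slot one-hot
    block in the fixed category order $(-1, 0, 1, 2)$, with additive
    Gaussian dither (mean 0, sd 0.02) on every slot, applied once at
    preprocessing time under a recorded seed.  Imputed (continuous)
    evidence values are rounded to the nearest category first.
4.  **Scaling**: the 23 score columns are min–max scaled with per-column
    bounds fitted on the training rows; out-of-range test values are
    clipped to $[0, 1]$; constant columns map to 0 with a warning.

The result is a $n \times 71$ matrix ($12 \times 4$ evidence slots + 23
scores) with a column manifest recording every column's provenance.  The
final width is a package convention (full one-hot, no dropped level): it
makes the evidence block decodable by argmax, which the tests exploit.

## Synthetic study conditions

No real labeled or knowledgebase data ship with the package; a generator
(`generate_dataset()`) emulates the structure the method assumes, so every
stage is testable offline.

* **Pool sizes** emulate the clinical setting the method targets: 1669
  oncogenic + 4829 benign labeled training variants, 1335 + 4829 test
  variants, and an unlabeled pool defaulting to 10,000 rows at desk scale
  (60,000 is config-reachable).
* **Score block**: each class is a mixture of 3 Gaussian clusters in the
  23-dimensional score space with a *shared* cluster geometry: base centres
  scatter with sd 1.5 per dimension, and each class sees every centre
  shifted by half of `class_separation = 1.2` along a fixed direction,
  with within-cluster sd 1.  Every cluster therefore straddles the class
  boundary.  This matters: if each class drew its own cluster centres
  independently in 23 dimensions, the clusters would be compact, far apart
  and class-pure, cluster identity would be a perfect label predictor, and
  even a handful of labels would saturate every classifier — the
  labeled-data-limited regime the method targets would be unreachable.
* **Evidence block**: drawn i.i.d. per column from class-conditional
  profiles over $(-1,0,1,2)$ — oncogenic $(.20,.32,.30,.18)$, benign
  $(.28,.36,.24,.12)$ — so evidence is somewhat more informative than the
  score block, mirroring the observation that evidence-based features
  dominate.
* **Missingness** is injected completely at random at rate 0.05.

These defaults were calibrated so that a 250-label budget leaves the
classifier visibly data-limited (test MCC in the 0.3–0.5 range and ROC-AUC
near 0.8, the regime the method is designed for) while the multi-cluster
geometry gives the unlabeled pool real structure to reveal.  What passing
tests on this generator do *not* show: robustness to the correlation
structure of real predictor scores (dbNSFP columns are strongly
correlated; ours are independent given the cluster), to informative
missingness, or to covariate shift between knowledgebases.

## Desk-scale problem sizes

The experiment drivers (`label_budget_sweep()`, `supervised_ablation()`,
`feature_group_ablation()`) default to 200 epochs over the 10,000-row
unlabeled pool with small networks — generator 16/16/16 hidden units on
16 noise dimensions, discriminator channels 4/4/8 — which recover the
qualitative phenomena (budget trend, semi-supervision benefit, saturation)
in minutes per run on one CPU.  The constructors' defaults remain the
full-scale sizes (generator 128/256/512 on 100 noise dimensions,
discriminator 32/64/128, 2000 epochs) for users who want the reference
protocol.  The supervised-only baseline in `supervised_ablation()` uses the
same discriminator architecture and the same number of optimizer updates,
differing only in what it sees — that makes the comparison an ablation of
the unlabeled data, not of capacity or schedule.

## Numerical and design notes

* **MCC**: implemented with the standard numerator
  $TP \cdot TN - FP \cdot FN$ (the denominator is the standard product of
  the four marginals).  Ratios with zero denominators (empty predicted or
  true classes) are reported as `NaN` with a warning rather than silently
  coerced to 0.
* **ROC-AUC** is the Mann–Whitney rank statistic (ties count half);
  **PR-AUC** uses step-wise summation $\sum_i (R_i - R_{i-1}) P_i$ with no
  linear interpolation.  Classification uses a strict `score > cutoff`
  rule, so a score exactly at the cutoff is benign.
* **Determinism**: every stochastic stage (simulation, dither, weight
  initialization, minibatch sampling, dropout, noise) draws from the R RNG
  under a recorded seed; two runs of the full pipeline with one seed are
  bitwise identical, which the test suite asserts.  Batch normalization
  uses batch statistics during training and running statistics (momentum
  0.1) at inference.
* **Checkpoints** are single JSON files of named arrays with doubles
  serialized at 17 significant digits — exact for IEEE-754 binary64 — so a
  reloaded model reproduces scores bitwise and the archive stays readable
  outside R.  The imputer's reference matrix is summarized (k and
  dimensions), not embedded.
* **Compiled hot path**: the forward/backward passes and fused
  per-minibatch gradient computations are C++ (RcppArmadillo); analytic
  gradients are pinned to finite-difference oracles in the test suite.
* **Embedding plot**: the interpretability figure projects generated,
  unlabeled and labeled variants onto the first two principal components —
  a deterministic linear embedding — rather than a stochastic neighbour
  embedding, and is decorative.
* **Open choices made**: min–max bounds are fitted on training rows only
  (test rows clip); evidence one-hot keeps all 4 levels; fresh noise is
  drawn for the discriminator's and the generator's step of each cycle;
  labeled/unlabeled sampling is with replacement (labeled) and
  without-replacement shuffling per epoch (unlabeled).

## Known limitations

The generator's independence assumptions understate real feature
correlation; the null-control and trend properties are statements about
this synthetic family, not about clinical performance.  Indels, non-coding
and splice variants have no feature representation here.  The 2000-epoch,
60,000-row configuration is supported but not exercised by the default
test suite; desk-scale results are noisier than the reference protocol's.
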