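---
title: "Fusing multi-scorer hypnograms: Soft-Agreement, soft-consensus smoothing, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing multi-scorer hypnograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(softstage)
```

## The problem

Clinical sleep staging assigns one of five AASM stages — W, N1, N2, N3, R —
to every 30-second epoch of a polysomnography night. Inter-rater agreement is
famously imperfect (N1 in particular is scored inconsistently), so reference
databases are increasingly scored by panels of five or six physicians.
Training an automatic stager on such a database raises two linked questions:

1. **Which single label do we train and evaluate against?** The standard
   answer is the per-epoch majority vote, with ties broken by the most
   reliable scorer.
2. **Should the target really be one-hot?** When three of five physicians say
   W and the others say N1 and N2, a one-hot W target throws away exactly the
   disagreement structure a probabilistic model ought to learn.

`softstage` implements the full chain: scorer-reliability ranking
(Soft-Agreement), majority-vote and soft-consensus construction, label
smoothing of the training target with the empirical scorer distribution,
and an evaluation suite covering per-subject agreement, calibration (ECE)
and hypnodensity similarity (ACS).

## Reliability and consensus

For scorer $j$ with one-hot annotations $y^j \in \{0,1\}^{K \times T}$, the
leave-one-out *probabilistic consensus* at epoch $t$ counts the valid votes
of the other $J-1$ scorers and divides by the maximum count:

$$ z^j_{\cdot,t} \;=\; \frac{\sum_{i \ne j} y^i_{\cdot,t}}{\max_k \sum_{i \ne j} y^i_{k,t}}, $$

so a stage holding the majority — or tied for it — scores exactly 1.
*Soft-Agreement* is this consensus evaluated at the scorer's own labels,
averaged over epochs:

$$ \mathrm{SA}_j \;=\; \frac{1}{T'} \sum_t z^j[y_j(t), t] \in [0,1], $$

where $T'$ counts the epochs at which both scorer $j$ and at least one other
scorer gave a valid (non-NC, non-missing) label — with complete annotation
panels $T' = T$. A scorer always inside the majority (or its ties) scores 1;
a scorer never matching any voted stage scores 0. Scorers are ranked per
recording by SA, ties kept in input order so ranking is deterministic.

The *soft-consensus* at epoch $i$ is the empirical vote distribution

$$ \mathrm{SC}_{i,k} \;=\; \frac{\#\{Y_i = k\}}{M_i}, $$

with $M_i$ the number of valid observations at that epoch. For the worked
panel $Y_i = [W, W, W, N1, N2]$:

```{r}
rec <- multi_scored_recording(matrix(c("W", "W", "W", "N1", "N2"), 1, 5))
soft_consensus(rec)$matrix
```

The *majority vote* is the per-epoch argmax of the soft-consensus. On tie
epochs the label comes from the most reliable scorer whose own vote is among
the tied stages; if that scorer's label is NC/missing or outside the tie we
descend the ranking (each tied stage has at least one vote, so this always
terminates). Descending past labels outside the tie keeps the invariant that
the consensus label always attains the row maximum of the soft-consensus.

### NC and missing annotations

Epochs scored NC ("not classified") by *every* scorer are removed
(`filter_nc_epochs()`); partially annotated epochs are kept, with the
per-epoch observation count $M_i$ reduced accordingly. NC and "-" (no
annotation) are distinct tokens with identical downstream treatment: both
simply leave the vote count. An epoch where a scorer voted NC but others
voted stages contributes nothing for that scorer; its NC never enters any
numerator or denominator. This is an interpretation choice — the source
conventions never state what a minority NC should count for — and it is the
only self-consistent reading of "occurrences divided by observations".

## Label smoothing with the soft-consensus

Classical uniform smoothing replaces the one-hot target by
$y^{LS_U}_{i,k} = y_{i,k}(1-\alpha) + \alpha/K$. Soft-consensus smoothing
uses the scorer distribution instead:

$$ y^{LS_{SC}}_{i,k} \;=\; y_{i,k}\,(1-\alpha) + \alpha \cdot \mathrm{SC}_{i,k}, $$

which at $\alpha = 0.5$ turns the one-hot W target of the worked example
into $[0.8, 0.1, 0.1, 0, 0]$. Training minimises the cross-entropy
$H(y, \hat p) = -\sum_k y_k \log \hat p_k$ (natural log; the base only
rescales the loss), averaged over the epochs of a batch and with predictions
clamped at $10^{-12}$ before the log. Because the smoothed target is affine
in $\alpha$, the LS$_{SC}$ loss is exactly the $(1-\alpha, \alpha)$ mixture
of the one-hot loss and the cross-entropy to the soft-consensus — a property
the test suite verifies numerically.

The $\alpha$ grids follow the convention that motivates them: uniform
smoothing searches $(0, 0.5]$ in steps of 0.1 (beyond 0.5 the uniform
component dominates), soft-consensus smoothing searches $(0, 1]$ including
$\alpha = 1$, where the target *is* the scorer distribution.
`smooth_soft_consensus()` additionally accepts $\alpha = 0$ as the
documented identity boundary, used in equivalence tests.

## Evaluation

* **Per-subject performance** against the majority-vote consensus: accuracy,
  per-class F1, macro F1, prevalence-weighted F1 and Cohen's kappa, computed
  per subject and aggregated as unweighted mean (± sd). Epochs are never
  weighted by how many scorers agreed.
* **ACS (averaged cosine similarity)** between the predicted hypnodensity
  $\hat p_{i,\cdot}$ and the soft-consensus hypnodensity:
  $\mathrm{ACS} = \frac{1}{N}\sum_i \cos(\mathrm{SC}_{i,\cdot},
  \hat p_{i,\cdot})$, in $[0,1]$ for nonnegative rows. This is the metric
  that measures whether a model reproduces the *disagreement structure* of
  the panel rather than just its argmax.
* **ECE (expected calibration error)** with $M = 10$ equal-width confidence
  bins $((m-1)/M, m/M]$ by default ($M$ configurable; a confidence of
  exactly 0 would fall in bin 1, though argmax confidence over 5 classes is
  always $\ge 0.2$). Empty bins contribute 0; the report also carries the
  overall mean confidence.
* **Significance of ACS differences** between models is assessed with a
  paired two-sided Wilcoxon signed-rank test across subjects. This test is
  our choice of convention, stated as such.

## The synthetic test bed

Real multi-scored PSG databases cannot ship with a package, so `softstage`
includes a generative stand-in with controllable ground truth:

* **Truth**: a first-order Markov chain over the five stages. The default
  kernel is built *reversibly* from target marginals $\pi$ (W 12.5%, N1
  5.9%, N2 48.7%, N3 14.0%, R 19.0% — typical of a healthy-adult panel
  database; the printed prevalences sum to 100.1% and are renormalised) and
  a symmetric stage-affinity matrix $S$:
  $P_{ij} = \varepsilon\, \pi_j S_{ij}$ off-diagonal. Detailed balance makes
  $\pi$ the stationary law *analytically*, so tests compare simulation
  against an eigen-decomposition oracle rather than a tuned constant. The
  default $\varepsilon = 0.2$ yields self-transition probabilities between
  0.57 (N1, the least persistent stage in real hypnograms) and 0.88.
* **Scorers**: scorer $j$ copies the truth with probability $r_j$, otherwise
  draws from the confusion-template row of the true stage; the default
  template concentrates errors on the W↔N1, N1↔N2, N2↔N3 and N2↔R
  confusions that dominate human disagreement. The default panel is $J = 5$
  scorers with reliabilities 0.6–0.9; `sim_config_partial()` gives a
  6-scorer panel with reliabilities 0.52–0.92 and 10%/2% missing/NC rates,
  emulating a partially annotated cohort. Per-epoch scorer accuracy has the
  closed form $r_j + (1-r_j)\,\mathrm{template}_{ss}$, which the tests
  recover within ±0.02 at $T = 10^5$.
* **Features**: one isotropic Gaussian draw per epoch centred on the true
  stage's centroid (default: centroids $2.5\,e_k$ in 5 dimensions, unit
  noise), giving a Bayes-attainable accuracy around 0.87 — the level of a
  competent human scorer. What the simulator does **not** emulate: real EEG
  spectra, stage-bout dwell-time distributions beyond first-order Markov,
  scorer-specific biases that persist across epochs, and within-night
  non-stationarity. Passing tests therefore demonstrate the correctness of
  the fusion/smoothing/metric machinery, not clinical performance.

Everything is a pure function of `(config, seed)`.

## The reference stager and the experiment protocol

The reference classifier is a deliberately minimal single-hidden-layer
feed-forward softmax network (default 16 hidden units, ReLU, inverted
dropout 0.2) trained by mini-batch Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
learning rate $10^{-2}$, batch 512) on the cross-entropy against arbitrary
row-stochastic targets. Training stops when the validation weighted F1 has
not improved for 5 consecutive passes (40 passes maximum); the
best-validation checkpoint is kept. Prediction supports MC-dropout: the
average of $S$ stochastic forward passes (default 30 when enabled), which
empirically softens the maximum confidence. The target-construction
machinery under study is architecture-agnostic; signal-level deep
architectures are out of scope here.

`run_experiment()` runs subject-level $k$-fold cross-validation (default
$k = 4$; fold $f$ is the test set, fold $f+1$ the validation set, the rest
training — hence $k \ge 3$). For each smoothing mode the weight $\alpha$ is
grid-searched on validation and one value retained per mode by mean
validation weighted F1 (ACS-based selection is available via `select_by`).
Training targets are each training subject's *own* majority-vote consensus,
smoothed per mode — the hidden simulation truth is never used. Test
predictions are pooled per subject and scored against the consensus
(performance, ECE, confidence) and the soft-consensus (ACS).

With the default database (40 subjects × 960 epochs, reliabilities 0.6–0.9)
the soft-consensus-smoothed model attains a higher mean test ACS than the
base model in every seed we run, with per-subject paired Wilcoxon p-values
near zero: the smoothed model reproduces the panel's disagreement structure
better than one-hot training does. These problem sizes keep a full
two-model, full-grid, five-seed battery within a few minutes on a single
CPU while leaving the effect unambiguous.

### A calibration caveat specific to small reference models

Uniform and soft-consensus smoothing are widely reported to *reduce* ECE for
deep architectures, whose softmax confidences run far above their accuracy.
Our minimal stager, trained with early stopping on tens of thousands of
epochs, converges close to the conditional distribution of the (noisy)
consensus labels and is already slightly **under**-confident (mean
confidence ≈ 0.84 against accuracy ≈ 0.86). Smoothing lowers confidence
further — the mechanism works exactly as designed, and the suite asserts the
confidence reduction — but from an underconfident starting point this
*increases* ECE rather than decreasing it. The calibration benefit of
smoothing is therefore a statement about overconfident models and should not
be expected from this test bed; the hypnodensity-similarity benefit (ACS) is
what transfers.

## Numerical choices and edge cases

* Stage order is fixed as W, N1, N2, N3, R (indices 1–5 in R) everywhere.
* Soft-consensus rows sum to 1 within $10^{-12}$; entries are exact
  multiples of $1/M_i$.
* `build_hypnodensity()` rejects rows whose sum is off by more than
  $10^{-6}$ and renormalises smaller deviations; rows already stochastic to
  $10^{-12}$ pass through bit-exactly.
* Cohen's kappa for two identical constant hypnograms ($p_e = 1$) is defined
  as 1.
* Degenerate inputs fail loudly with located errors: unknown tokens name
  their row and column, all-invalid epochs name the epoch, zero-norm ACS
  rows name the epoch.

## Reproducibility

All simulator and training randomness flows through explicit integer seeds;
datasets, experiments and CLI runs are bit-reproducible from their
provenance (config + seed), and every artifact-producing CLI run writes a
`.provenance.json` sidecar.
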