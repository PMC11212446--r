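---
title: "Noise-robust training for tabular clinical classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-robust training for tabular clinical classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Diagnostic labels in electronic health records are imperfect. When the
reference test itself has limited sensitivity — PCR for respiratory viral
infection is the motivating example, with sensitivity estimated around
80–90% while specificity is near-perfect — a fraction of true cases enters
the training data labeled negative. This noise is *class-conditional and
asymmetric*: the false-negative rate among true cases far exceeds the
false-positive rate among controls, and because cases are rare (prevalence
around 5% in emergency-department triage cohorts), even a modest
false-negative rate removes a large share of the positive signal.

A classifier trained by plain cross-entropy on such labels eventually
*memorizes* them: its confidence in the incorrect labels rises over
training, and test performance degrades as the corruption level grows.
`noisytab` implements three mitigation methods originally developed for
image classification, adapted to tabular clinical data, together with the
machinery needed to study them honestly: a synthetic cohort generator with
known clean labels, an exact corruption protocol, a leakage-free
preprocessing pipeline, an evaluation harness with bootstrap uncertainty,
and memorization diagnostics.

## The methods

All three methods sit on top of a fully connected network with ReLU hidden
layers and a single sigmoid output unit, trained with Adam.

**Label smoothing** replaces the one-hot target with \(1-\epsilon\) on the
assigned class and \(\epsilon/(C-1)\) elsewhere, discouraging extreme
confidence in any single (possibly wrong) label. One description of this
method samples \(\epsilon\) uniformly on \([0,1]\); taken per example that
would invert labels whenever \(\epsilon > 0.5\), which cannot be intended.
The package therefore defaults to a fixed, tuned \(\epsilon\)
(`smoothing_spec(mode = "fixed")`) and offers a per-epoch resampled mode
with \(\epsilon \sim U(0, 0.5)\) for users who want the stochastic variant.

**Mix-up** trains on convex combinations of sample pairs:
\(x_{mix} = \lambda x_1 + (1-\lambda) x_2\),
\(y_{mix} = \lambda y_1 + (1-\lambda) y_2\), with
\(\lambda \sim \mathrm{Beta}(\alpha, \alpha)\). The package draws one
\(\lambda\) per batch and mixes each batch with probability `p_apply`,
pairing rows against a seeded permutation of the same batch. Per-batch
(rather than per-sample) \(\lambda\) is a deliberate choice: the method
description applies a per-batch mix probability, which implies batch-level
mixing; the alternative is noted as an open variant.

**Neighbour consistency regularization (NCR)** penalizes, for every sample
\(i\) in a batch of size \(m\), the divergence between its predicted class
distribution \(\sigma(z_i)\) and the similarity-weighted mixture of the
predictions of its \(k\) nearest neighbours in a hidden-layer
representation space:

\[
L_{NCR} = \frac{1}{m}\sum_{i=1}^{m}
  D\!\left(\sigma(z_i)\,\Big\|\,
  \sum_{j \in NN_k(v_i)} \frac{s_{ij}}{\sum_{l \in NN_k(v_i)} s_{il}}\,
  \sigma(z_j)\right),
\qquad
s_{ij} = \frac{v_i^\top v_j}{\lVert v_i\rVert\,\lVert v_j\rVert},
\]

with self-similarity set to zero before neighbour selection and the
selected similarities renormalized to a probability distribution. The
total objective is \(L_{total} = L_{CE} + \alpha\,L_{NCR}\) — the additive
form, not the convex combination \((1-\alpha)L_{CE} + \alpha L_{NCR}\) used
elsewhere in the NCR literature. \(D\) is the KL divergence by default,
with Jensen–Shannon and mean-absolute-error variants
(`ncr_spec(divergence = )`).

Numerical choices worth knowing:

* The KL direction is exactly \(D(\sigma(z_i)\,\|\,\text{mixture})\);
  probabilities are clamped to \([10^{-7}, 1-10^{-7}]\) before any
  logarithm.
* Neighbours are found within the mini-batch; similarity ties break toward
  the lower row index, making runs bit-reproducible.
* Post-ReLU representations make all cosines non-negative; negative values
  (impossible in practice, possible if a caller supplies arbitrary
  representations) are clamped to zero before normalization and their
  subgradient taken as zero.
* A sample whose selected neighbour similarities are all zero contributes
  zero loss and zero gradient.
* With a single sigmoid output, the two-class distribution required by the
  divergence is materialized as \((1-p, p)\).

Because no automatic-differentiation framework is involved, the gradients
of \(L_{NCR}\) with respect to both the logits and the representations
(through the similarity weights) are derived analytically and
backpropagated into every layer; unit tests verify them against central
finite differences to machine precision, and a dedicated test confirms the
gradient reaches the earliest layer's weights.

**Warm-up.** The NCR term is exactly zero for the first `warmup_epochs`
epochs (default 30): the network first learns the broad class structure
from the noisy labels with plain cross-entropy, and the regularizer
switches on once representations are informative enough for neighbourhoods
to mean something. Training histories record the CE and NCR terms
separately so the boundary is visible, and a property test checks that
epochs before the boundary are bit-identical to a baseline run.

## The synthetic cohort generator

Real triage cohorts of this kind are access-restricted, so the package
ships a generator that emulates their statistical shape rather than any
specific dataset: continuous lab/vital-style features, strong class
imbalance, missing values, and (after injection) asymmetric label noise.
Each class is an equicorrelated multivariate normal: feature \(j\) of
sample \(i\) is \(x_{ij} = \mu_c + \sqrt{\rho}\,f_i + \sqrt{1-\rho}\,
e_{ij}\), so all features have unit variance and pairwise correlation
\(\rho\), and the positive-class mean is shifted by `separation` in every
feature. This family was chosen because its Bayes discriminant is linear
and closed-form — `bayes_auroc()` gives the exact performance ceiling
\(\Phi(\Delta/\sqrt 2)\) with
\(\Delta^2 = \delta^2 d/(1-\rho+\rho d)\) — which the tests use as an
oracle.

Defaults (chosen once, as a realistic triage-like regime): n = 6,000
presentations, 20 features, prevalence 0.05, separation 1.0, correlation
0.3, missing rate 0.15. With these values the Bayes ceiling is 0.889,
matching the high-but-imperfect discrimination typical of blood-test/vital
-sign triage models. The default corruption protocol flips 10–40% of true
cases to negative and a constant 0.5% of controls to positive, mirroring
the sensitivity/specificity asymmetry of the reference test.

What the generator does *not* emulate: real feature lists and their mixed
scales, informative missingness (missing entries are completely at random,
consistent with a pipeline that imputes medians and does not model the
mechanism), temporal drift across pandemic waves, and site effects.
Passing the package's tests therefore demonstrates that the methods behave
as designed under controlled, known noise — not that any particular
hospital deployment will see the same gains.

Flip counts use round-half-to-even on rate × class-count, so corruption is
an exact, deterministic function of the noise specification; flips are
always computed from the clean labels, making injection idempotent and
re-corruption non-compounding.

## Preprocessing

Median imputation and standardization are fitted on the training split
only and replayed everywhere (`fit_preprocess()` / `apply_preprocess()`),
so no test statistics leak into training. "Population median" is read as
the training-population median — the only leakage-free interpretation.
Even-length medians are the mean of the two central order statistics.
Constant training features raise an error by default
(`on_constant = "unit_scale"` passes them through unscaled instead),
because silently dividing by zero is worse than either option.

## Evaluation harness

* **Threshold tuning**: candidates are midpoints of consecutive sorted
  unique validation scores plus one candidate below the minimum and one
  above the maximum; the returned threshold is the *highest* one whose
  validation sensitivity still meets the target (default 0.85, the
  clinically motivated triage operating point), i.e. the most specific
  admissible point. With target 0 the above-maximum candidate is returned.
* **AUROC** is the Mann–Whitney rank statistic with midranks (ties count
  one half); **AUPRC** is step-integrated average precision with tied
  scores entering together. Both are checked against exhaustive pair
  enumeration and against an independent ROC implementation in the tests.
* **Bootstrap CIs** are percentile intervals over 1,000 test-set resamples
  (the construction is not further specified in the source material;
  percentile is the simplest defensible choice). Single-class resamples
  are redrawn and counted; a metric undefined on more than half of the
  resamples is an error, not a number.
* **Paired comparison**: both models are evaluated on the *same* resample
  indices; with candidate A and comparator B, p is the fraction of
  resamples on which A fails to beat B, ties counted one half — so
  identical models give p = 0.5 and uniform dominance gives p = 0. The
  report header states this orientation.

## Experiment runner and diagnostics

`run_sweep()` crosses noise levels × methods × seeds. Within a (noise
level, seed) cell every method sees the identical corrupted training
split — corruption depends only on the sweep seed, repetition and noise
level — and evaluation always uses the clean test labels, mirroring a
design where only training data is corrupted and test sets carry reference
labels. Whether corrupted labels should be redrawn per method is not
specified in the source design; fixing them per cell is the only choice
that makes the method comparison paired, so that is what the runner does.
The validation split is left clean (it drives threshold adjustment, not
learning); this interpretation is noted here deliberately.

The consistency statistic reported by `summarize_sweep()` is the standard
deviation, across noise levels, of the per-level seed-mean AUROC: a
noise-robust method keeps it small.

Two mechanism-level diagnostics mirror the memorization story:

* `similarity_strata()` partitions pair similarities in the NCR
  representation space into four disjoint, exhaustive strata by
  label agreement × label correctness; `similarity_gap()` summarizes class
  separation as mean(same-label clean) − mean(different-label clean).
  Pair subsampling (default 100,000 pairs, seeded) keeps this desk-scale;
  the full-pair mode is used automatically below the budget.
* `confidence_trace()` tracks the per-epoch mean predicted confidence in
  the *assigned* (possibly wrong) label, separately for clean and
  mislabeled training samples: a memorizing model's mislabeled-sample
  confidence climbs; a robust one keeps it low.

## Problem sizes and defaults

The default sweep (n = 6,000, 20 features, hidden layers 32/32, batch 64,
learning rate 5e-3, 60 epochs, k = 10, NCR weight 1, warm-up 30 epochs,
5 seeds) was sized so a full five-level noise sweep runs in minutes on a
single CPU while leaving a clear gap between the Bayes ceiling and what a
smallish network achieves under noise. k ≈ 10 and a ~30-epoch warm-up are
the values that work best in the source setting; the network architecture
and optimizer hyperparameters for that setting are not public, so they are
exposed as configuration rather than asserted as defaults. Batch-local
neighbour search (never across batches) is both the formulation printed in
the objective and the only one compatible with mini-batch training.

## Known limitations

* The generator's Gaussian, MCAR, equicorrelated structure is deliberately
  idealized; conclusions about real EHR cohorts require real data.
* NCR assumes neighbourhoods in the representation space are
  class-consistent; under extreme noise or tiny batches the neighbour
  mixture itself is unreliable (the `k < batch_size` precondition is
  enforced, and the NCR term is skipped on a trailing batch smaller than
  k + 1).
* Label-correction, co-training and robust-loss families are out of scope,
  as are calibration and decision-curve analyses.
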