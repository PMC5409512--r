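---
title: "Methods: PU learning for drug-target retrieval with SAE embeddings and a biased SVM"
author: "idtp package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PU learning for drug-target retrieval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idtp)
```

## The problem

Known drug-target proteins (DTPs) are a small, positively labeled set; the
remaining "non-target" proteins (NDTPs) are not verified negatives — some of
them are unrecognized true targets. This is the positive-unlabeled (PU)
setting: the unlabeled set is a mixture

$$h_u(x) = \alpha\, h_+(x) + (1 - \alpha)\, h_-(x),$$

where $h_+$ and $h_-$ are the class-conditional distributions over protein
properties and $\alpha$ is the (unknown) contamination fraction of hidden
positives. When $\alpha$ is small, $h_u \approx h_-$, which justifies the
working device of treating unlabeled records as negatives during training
while biasing the classifier toward recalling positives. The deliverable of
the analysis is the *doubtful* set: unlabeled proteins the fitted classifier
flags as positive, i.e. candidates for experimental validation.

`idtp` implements the full framework: mixed-type property preprocessing,
Kolmogorov–Smirnov property screening, a stacked auto-encoder (SAE)
embedding, a biased support vector machine (BSVM), a repeated
stratified-hold-out experiment driver, and a contamination-mixture simulator
with hidden ground truth.

## Preprocessing

Each protein record carries 31 continuous and 8 nominal physicochemical
properties in the reference shape. Continuous properties are z-scored,
$z_i = (x_i - \mu)/\sigma$; nominal properties with $d$ states become
$d$-dimensional one-hot bit vectors. Concatenation in schema order gives a
283-column matrix for the reference shape.

Numerical choices:

* **Standard deviation convention.** $\sigma$ uses the population divisor
  $n$, matching the "mean of the population" phrasing of the normalization;
  `sd_type = "sample"` switches to $n-1$. A constant property
  ($\sigma = 0$) is an error, not silently dropped.
* **Fit scope.** By default the statistics are fitted on the *whole* table
  (positives and unlabeled) before any split, deliberately reproducing the
  original protocol, which normalizes the complete dataset up front. This
  leaks marginal statistics across the later train/test split; the `rows`
  argument of `fit_preprocessor()` provides the strict alternative of
  fitting on training rows only.
* **Missing values** are rejected with row/property context rather than
  imputed; the framework assumes complete property tables.

KS screening (`ks_screen()`) runs a two-sample test per property between
positives and unlabeled records, via the asymptotic two-sample
Kolmogorov–Smirnov test. Nominal properties are screened on their integer
state index with a warning: the KS test is conservative on discrete data,
but screening every property uniformly mirrors the one-p-value-per-property
reporting of the original study. Exact p-values are not attempted; with
thousands of records the asymptotic approximation is the practical choice.

## Stacked auto-encoder embedding

A single auto-encoder maps $y = f(Wx + b)$ and reconstructs
$z = g(\tilde W y + \tilde b)$, trained to minimize the squared
reconstruction error $\lVert x - z\rVert_2^2$ (summed binary cross-entropy
is available for 0/1 inputs). Auto-encoders are stacked greedily: each AE is
trained on the hidden output of the previous one, down to the bottleneck of
the palindromic size list. The default architecture is
$d\!-\!140\!-\!10\!-\!140\!-\!d$, so proteins embed into 10 dimensions.

Training follows the reference protocol: up to 100 epochs, minibatches of
100, the adadelta optimizer, mean-square loss, and a 70/30 train/validation
row split used *only* for early stopping — the embedding itself is fitted on
all rows, positives and unlabeled alike, as the original protocol trains the
SAE on the entire dataset.

Design choices the original description leaves open, resolved here:

* **Activations.** Hidden layers default to sigmoid; the reconstruction
  layer of the first AE is linear, because z-scored inputs are signed and a
  linear output with mean-square loss is the consistent likelihood choice.
  Deeper AEs reconstruct sigmoid outputs and therefore use sigmoid decoders.
  Both are configurable (`sigmoid`, `linear`, `relu`).
* **Greedy only.** Stacking uses purely greedy layerwise pretraining and the
  bottleneck output directly; an optional end-to-end `fine_tune` pass exists
  but defaults off, since the embedding — not a supervised network
  initialization — is the goal.
* **Early stopping.** "Validation error begins to increase markedly" is
  quantified as: stop after `patience = 5` consecutive epochs without an
  improvement of at least `min_delta = 1e-4` over the running minimum.
* **Optimizer.** Adadelta uses its canonical defaults (decay 0.95,
  $\epsilon = 10^{-6}$); plain SGD and Adam are available because the
  optimizer is a named strategy. Training that produces non-finite errors
  (a diverging learning rate) stops with a warning instead of propagating
  NaNs.
* **Initialization.** Uniform Glorot-style weights scaled by fan-in/fan-out,
  drawn from the seeded RNG; biases start at zero. Given the seed, training
  is bit-reproducible.

In the linear-activation limit a single bottleneck AE solves the same
problem as rank-$k$ PCA; the test suite exploits this, requiring the
converged reconstruction error on a rank-structured Gaussian fixture
($n = 500$, $d = 20$, $k = 5$) to come within 10% of the exact top-$k$
principal-component residual computed by SVD.

## Biased SVM

The classifier is a soft-margin kernel SVM with asymmetric slack penalties:

$$\min_{w, b, \zeta}\ \tfrac12 w^\top w
  + C_+\!\!\sum_{i \le k}\zeta_i + C_-\!\!\sum_{i > k}\zeta_i
  \quad \text{s.t.}\quad y_i(w^\top\phi(x_i) + b) \ge 1 - \zeta_i,\ \zeta_i \ge 0,$$

with the $k$ labeled positives carrying $C_+$ and the unlabeled-as-negative
records carrying $C_-$. Choosing $C_+ > C_-$ makes missed positives
expensive and relieves the 1:10 class imbalance. The RBF kernel
$K(u,v) = \exp(-\gamma\lVert u-v\rVert^2)$ is the default (the reference
parameterization reports a $\gamma$); a linear kernel is provided for tests.

The dual, with per-class box constraints $0 \le \alpha_i \le C_{class(i)}$
and $\sum_i \alpha_i y_i = 0$, is solved by sequential minimal optimization
with maximal-violating-pair working-set selection. The solver stops when the
KKT violation drops below `tol` (default $10^{-3}$; the oracle tests run at
$10^{-8}$), with an iteration budget of `max_passes` sweep-equivalents
(default $10^4$, error with diagnostics on exhaustion). The offset $b$ is
averaged over free support vectors, falling back to the violating-pair
midpoint. Every fit is verified in the test suite against a dense quadratic
programming oracle (`kernlab::ipop`) and against a reference class-weighted
SVM (`e1071::svm`), to $10^{-6}$ on the dual objective and decision values.

A decision value of exactly zero predicts the negative class: conservative
for retrieval, since borderline proteins are not promoted to candidates.

The balance heuristic $C_+|P| = C_-|N|$ is exposed as
`heuristic_ratio()` and as the `ratio_locked` grid mode, which searches only
$(\gamma, C_-)$; it is not enforced when both penalty lists are given,
because the reference optimal parameter sets do not satisfy it exactly.
Grid search scores candidates by positive-class F1 on the training set
itself (the primary protocol) or by stratified 5-fold cross-validated F1
(the comparison variant), visiting candidates in ascending
$(\gamma, C_-, C_+)$ order with first-maximum tie-breaking, so results are
deterministic.

## Experiment protocol

`run_experiment()` repeats, for each of `n_iterations` (10 in the reference
protocol) independent iterations:

1. build the representation — `sae` (retrain the SAE with a fresh seed and
   embed), `wrapper` (sequential forward selection on the training rows,
   scored by 5-fold CV F1 of the BSVM), or `origin` (full encoded matrix);
2. stratified 70/30 split per class, train counts rounded half-up;
3. grid search on the training split, refit the winner, evaluate on both
   splits (F1 and recall of the positive class, precision of the predicted
   negatives $TN/(TN+FN)$);
4. retrieve the doubtful set: unlabeled records predicted positive anywhere
   (training ∪ testing portions), reported as a proportion of all unlabeled
   records.

Summaries report the mean and *population* variance (divisor $n$,
configurable) of each metric across iterations, mirroring the
mean-(variance) reporting convention of the reference tables. Training-set
metrics come from the grid winner refitted on the full training split, and
the SAE is retrained every iteration — both points the original text leaves
ambiguous; retraining matches its remark that randomness enters through
both the SAE training and the sampling process. The wrapper baseline is
instantiated as sequential forward selection because the original citation
gives no recipe; forward CV-driven selection is the canonical wrapper.

Everything derives from one master seed (per-iteration seeds are drawn from
it), so a run is bit-reproducible end to end.

## The simulator

`simulate_pu_dataset()` generates PU datasets with exactly the mixture
structure the framework assumes. Labeled positives come from $h_+$; each
unlabeled record is drawn from $h_+$ with probability $\alpha$, else $h_-$,
and its true class is recorded separately from the table so pipeline code
cannot consume it. Informative continuous features are unit-variance
Gaussians with class means `effect_size` apart; informative nominal features
tilt the positive class toward the first state with weight
$e^{\text{effect\_size}}$; uninformative features are identical across
classes. Defaults mirror the real study's shape: 517 positives, 5376
unlabeled, 31 continuous properties, 8 nominal properties whose state
counts (4×31 + 4×32 = 252) were chosen so the encoded dimension reproduces
283, and $\alpha = 0.23$ — the retrieved proportion reported for the real
data, used here as a convenient default for a free parameter (the original
analysis never estimates $\alpha$; its 23% is an output, not a prior).

What the simulator does *not* emulate: correlations among properties induced
by shared sequence features, heavy-tailed or skewed property marginals, and
any biochemical meaning of the states. Passing tests therefore demonstrate
that the machinery recovers planted structure under the stated mixture
assumption, not that the biological conclusions transfer.

## Problem sizes in tests and the acceptance script

The shipped checks run on scaled-down mixtures chosen once as
representative: recovery checks use $n_+ = 100$, $n_u = 1000$,
$\alpha = 0.1$, `effect_size = 2` (strong separation) with a 16-column
schema and a 16–8–4–8–16 SAE; the ten-iteration protocol runs at
$n_+ = 100$, $n_u = 800$, $\alpha = 0.23$ with an 18-column schema. These
sizes exercise every stage — embedding, asymmetric-penalty fitting, grid
search, retrieval — while keeping the full suite interactive. The full
reference shape (5893 × 283) is exercised through preprocessing and
splitting, which are exact at any size.

## Known limitations

* The SMO solver and SAE trainer are plain R; they are comfortable at the
  shipped problem sizes ($n$ in the low thousands) but not tuned for
  datasets orders of magnitude larger.
* Decision values are uncalibrated margins, not probabilities; ranking the
  doubtful list by decision value is supported, thresholding it
  probabilistically is not.
* $\alpha$ is never estimated from data; the retrieved proportion is a
  classifier output whose agreement with $\alpha$ in simulations depends on
  class separation.
* PU recovery guarantees degrade as $\alpha$ grows or separation shrinks;
  with the unlabeled-as-negative device the learned boundary is biased
  toward $h_u$, not $h_-$.
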