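---
title: "Calibrated uncertainty for bioactivity classifiers: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated uncertainty for bioactivity classifiers: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures `qsarcalib` implements,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where the design was genuinely open. It states no empirical result
that the test suite and `scripts/acceptance.R` do not themselves compute.

## The modelling problem

The package targets single-task binary bioactivity classification: a
compound, represented as a sparse binary circular-fingerprint vector
$x \in \{0,1\}^d$ (default $d = 32{,}768$, radius 3), is labelled active
($y = 1$) or inactive, typically by thresholding pIC50 (a compound is
active iff $\mathrm{pIC50} \ge$ threshold; the boundary is inclusive).
The quantity of interest is not only the ranking of compounds but the
*calibration* of the predicted probability $f(x)$: among compounds with
$f(x) \approx 0.7$, about 70% should be active.

## Cluster-atomic cross-validation

Random splits overestimate prospective performance because test compounds
are near-duplicates of training compounds. The package instead:

1. clusters compounds by single-pass **leader (sphere-exclusion)
   clustering** on Tanimoto similarity $|a \cap b| / |a \cup b|$: compounds
   are visited in a seeded random order; each joins the first existing
   leader with similarity $\ge t$ (default $t = 0.6$), else founds a new
   cluster. Every member is within the threshold sphere of its leader and
   leaders are mutually dissimilar;
2. assigns **whole clusters** to five folds, largest cluster first, each
   into the currently smallest fold with seeded tie-breaking. Pure random
   assignment of clusters can produce badly unbalanced folds when cluster
   sizes are heavy-tailed; the greedy balancer keeps fold sizes close while
   remaining cluster-atomic;
3. uses three folds for training, one for validation (early stopping,
   hyperparameter tuning, Platt fitting, prior tuning) and one for
   testing.

The clustering threshold is a configurable stand-in: the published fold
generation procedures this mimics do not pin a single value, and $0.6$ is
a conventional choice for ECFP-like fingerprints. The all-zero fingerprint
is rejected (Tanimoto is undefined for it); rows that featurize to
all-zero are dropped with a warning.

## Baseline classifier

A two-layer perceptron: $\mathrm{logit}(x) = W_2^\top
\mathrm{ReLU}(W_1^\top x + b_1) + b_2$, probabilities through a sigmoid,
clipped to $[\varepsilon_p, 1-\varepsilon_p]$ with
$\varepsilon_p = 10^{-7}$ so that cross-entropy and logit transforms stay
finite. Dropout acts on the hidden layer with inverted scaling
($1/(1-r)$ at train time), so deterministic inference needs no rescaling.

Training minimizes BCE by Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$) with
*decoupled* weight decay applied to the weight matrices only. The
optimizer is a package choice — the training framework the approach
descends from does not pin one in its description — and Adam is the
field's default for sparse-input MLPs. Early stopping evaluates
validation BCE each epoch, restores the best snapshot, and stops after
`patience` (default 10) non-improving epochs; `patience = 0` stops at the
first non-improving epoch. Initialization is fan-in-scaled uniform,
seeded per repeat; a single config seed controls initialization,
shuffling and dropout masks, making every trained model bit-reproducible.
`train_mlp(..., restore_best = FALSE)` returns the final-epoch parameters
instead — a diagnostic knob used by the overfitting probe in the test
suite.

## Train-time uncertainty quantification

Both methods discretize the posterior predictive average
$p(y \mid x, D) \approx \frac{1}{M} \sum_m p(y \mid x, \theta_m)$:

- **MC dropout**: $M$ stochastic forward passes (default 100) with
  dropout active at inference; the mean is taken in probability space.
- **Deep ensembles**: $M$ networks (default 50) differing only in their
  initialization seed — identical data and split, no bagging — averaged
  unweighted in probability space.

Probability-space averaging is the direct reading of the predictive
average above; logit-space access to these models exists only through the
logit transform of the averaged probability (see Platt stacking below).

## The HMC Bayesian last layer

The proposed method freezes the trained network body and replaces the
output layer by a Bayesian logistic regression on the hidden features
$H \in \mathbb{R}^{n \times h}$ of the training folds. With
$\tilde H = [H \,|\, 1]$ and an isotropic Gaussian prior of precision
$\tau$ over all $h{+}1$ parameters (bias included — the simplest reading
of a single prior over "the model parameters", and one tunable knob):

$$\log p(\theta \mid D) = \sum_i \big[ y_i \log \sigma(z_i) + (1-y_i)
\log(1-\sigma(z_i)) \big] - \tfrac{\tau}{2}\lVert\theta\rVert^2 + C,
\qquad z = \tilde H \theta .$$

- **MAP**: damped Newton with step halving on the strictly concave log
  posterior, run to a relative gradient norm of $10^{-6}$; deterministic.
- **Curvature**: the observed information
  $\tilde H^\top \mathrm{diag}(\sigma(z)(1-\sigma(z)))\tilde H + \tau I$,
  symmetric positive definite for any $\tau > 0$.
- **Sampling**: vanilla HMC, one chain, no step-size adaptation and no
  NUTS. Momenta are drawn from $N(0, M)$; the kinetic energy is
  $\tfrac12 p^\top M^{-1} p$; leapfrog integrates $L$ steps of size
  $\varepsilon$; a Metropolis step accepts with
  $\min(1, e^{-\Delta H})$. Trajectories that hit non-finite energies are
  rejected and counted; the sampler aborts if more than half of all
  iterations diverge. Defaults mirror the production protocol (500
  burn-in, 1000 samples, $L = 1200$, $\varepsilon = 0.01$); desk-scale
  runs in the tests and the acceptance script shrink $L$ to 20–30 and
  raise $\varepsilon$ to ~0.1, which keeps runtimes in seconds at
  equal statistical quality for these small posteriors.
- **Preconditioning**: the mass matrix is set to the MAP Hessian —
  equivalently the *inverse* mass matrix to its inverse. With kinetic
  energy $\tfrac12 p^\top A p$ for a supplied inverse mass $A$, the
  position dynamics obey $\ddot q = -A\,\nabla U$; only
  $A = \mathrm{Hessian}^{-1}$ cancels the posterior curvature (giving
  $\ddot q \approx -q$ near the mode), whereas using the Hessian itself as
  $A$ *squares* the condition number. The package therefore passes the
  inverse Hessian as the inverse mass; a jitter of $10^{-8} I$ is added
  before the Cholesky factorization if it fails. The test suite verifies
  the effect directly: on a condition-100 Gaussian, curvature
  preconditioning lowers lag-1 sample autocorrelation relative to identity
  mass at equal $(L, \varepsilon)$.
- **Prediction**: $\frac{1}{M}\sum_m \sigma(\tilde h(x)^\top \theta_m)$,
  strictly inside $(0,1)$.
- **Prior tuning**: $\tau$ is selected on the validation fold over a
  log-spaced grid (default $10^{-3} \dots 10^{3}$), minimizing validation
  BCE by default. The criterion is a package choice — the protocol this
  follows does not name the metric — and BCE is chosen because it is the
  training loss and a proper score; ties break toward the larger (more
  regularizing) $\tau$.

## Platt scaling and stacking

`fit_platt` fits $\sigma(a \cdot \mathrm{logit} + b)$ to the validation
labels by unregularized maximum likelihood (IRLS) — with two parameters
and hundreds of calibration points, regularization is unnecessary.
Platt's classic smoothed targets $(N_+{+}1)/(N_+{+}2)$, $1/(N_-{+}2)$ are
available behind `smooth = TRUE` but off by default. A non-positive fitted
slope warns (the classifier ranks worse than chance) but does not fail.
For averaged-probability models the "logit" is the logit transform of the
clipped mean probability; `stack_platt` fits on the validation
probabilities and applies to the test probabilities. Whenever $a > 0$ the
map is strictly monotone, so AUC is unchanged.

A note on temperature recovery: `gen_miscalibrated_predictions` reports
$\sigma(\mathrm{logit}(p)/T)$ for calibrated latent $p$, i.e. it
*multiplies* logits by $1/T$. The maximum-likelihood Platt slope on those
reported logits converges to $a = T$ — the inverse of the applied
distortion factor — which is what the tests assert ($T = 0.5$ recovers
$a \approx 0.5$).

## Metrics

All metrics are computed on the test fold with a shared bin count
$B = 10$, the dominant convention in the calibration literature; $B$ is
exposed everywhere as `n_bins`.

- **ECE** (fixed width): half-open bins $[k/B, (k{+}1)/B)$, the last bin
  closed so that a probability of exactly 1 is counted.
- **ACE** (equal count): predictions are stably sorted and cut into $B$
  contiguous groups whose sizes differ by at most one; *tied predictions
  stay together in the bin of their first member*. The tie rule matters:
  without it a constant prediction is scattered across bins and the
  degenerate case — a model that always predicts the base rate is
  perfectly calibrated — would be violated by the estimator itself.
- Both feed $CE = \frac{1}{N}\sum_b n_b\,|acc(b) - conf(b)|$; empty bins
  contribute zero.
- **Brier decomposition** (binned): reliability
  $\frac1N \sum_b n_b (conf_b - acc_b)^2$, resolution
  $\frac1N \sum_b n_b (acc_b - \bar y)^2$, uncertainty
  $\bar y (1-\bar y)$ with $\bar y$ the empirical base rate of the
  evaluated set. The identity $BS = REL - RES + UNC$ is exact exactly when
  predictions are constant within bins; the tests assert it there to
  $10^{-12}$.
- **AUC**: Mann–Whitney rank form, ties counting one half.
- **Comparisons**: two-sided Student t-tests at $p = 0.05$; paired between
  the baseline and its seed-matched modifications (Platt, MC dropout,
  Bayesian last layer and its stacked variant), Welch-unpaired otherwise
  (ensembles are trained separately with their own seeds). Zero-variance
  paired differences raise a degenerate-test error rather than returning a
  meaningless statistic.

On the often-cited robustness advantage of ACE over ECE: with the
$n_b$-weighting above, the *aggregate* bootstrap variances of the two
estimators are close even for heavily skewed prediction distributions —
the weighting suppresses exactly the sparse bins that are noisy. The
instability appears at the per-bin level, where the largest per-bin gap
fluctuates far more under fixed-width binning; the property test asserts
that formulation.

## Model selection and the study engine

`grid_search` enumerates the Cartesian product of hidden sizes, dropout
rates, learning rates and weight decays (defaults span the
under-/over-regularization axis: hidden $\{50, 200, 1000\}$, dropout
$\{0, 0.2, 0.4, 0.6\}$, learning rate $\{10^{-3}, 10^{-4}\}$, weight decay
$\{0, 10^{-5}, 10^{-4}\}$), trains each configuration over seeded repeats
(default 10) and averages one of four validation metrics: maximize
accuracy or AUC, minimize BCE or ACE. Ties break to the first
configuration in grid order; a training failure skips that configuration
with a warning rather than aborting the search. MC dropout shares the
hyperparameters selected for the baseline.

`run_study` derives the baseline modifications from the *same* trained
repeats (hence the paired tests), trains ensembles separately with fewer
repeats (default 5 vs 10), scores everything with `evaluate_model`, and
flags per metric the best method and those statistically indistinguishable
from it.

## The synthetic-data generator

`gen_fingerprint_dataset` emulates the statistical structure the methods
assume: sparse binary fingerprints (~40 bits per compound) organized into
chemical series — each cluster has a template bit set, members copy
template bits with probability `within_cluster_overlap` (default 0.7) and
add Poisson-many private bits — plus a sparse Gaussian ground-truth weight
vector and an intercept solved by bisection so that the mean of
$\sigma(w^\top x + b)$ hits `active_ratio_target` exactly (default 0.25,
matching the common single-target active ratio; smaller ratios are a
parameter away). Labels are Bernoulli draws, optionally flipped with
probability `label_noise`. Cluster sizes are drawn heavy-tailed to
exercise the fold balancer.

What it does **not** emulate: real substructure correlation between bits,
assay noise structure, activity cliffs, or the bit-collision statistics of
hashed fingerprints. Passing tests on this generator therefore validate
the *machinery* — splits, training, sampling, calibration arithmetic — not
prospective performance on real assay data. The default
`true_weight_sparsity` of 0.05 makes the task hard at small feature
counts; test fixtures and the acceptance script raise it (0.2–0.25) where
a competent classifier is a precondition of the property under test, since
real fingerprint–activity relationships are strongly learnable.

`gen_miscalibrated_predictions` draws latent calibrated probabilities from
a Beta distribution parameterized by mean (`base_rate`) and concentration
(default 2 — dispersed, so all bins are exercised), labels from those
probabilities, and reports temperature-distorted probabilities:
$T < 1$ overconfident, $T > 1$ underconfident, $T = 1$ calibrated by
construction.

## Problem sizes and numerical choices

The test suite and the acceptance script run desk-scale versions of the
study: datasets of 300–5000 compounds with 48–1024 fingerprint bits,
hidden layers of 4–512 units, ensembles of 2–10 members, HMC chains of a
few hundred to 20,000 samples with $L$ = 10–30. These sizes are chosen so
the full suite completes in minutes while every statistical assertion
retains adequate power; the package itself scales to the production
defaults (32k bits, 50-member ensembles, $L = 1200$) unchanged. Oracles in
the tests are independent re-derivations: set-arithmetic Tanimoto, an
$O(n^2)$ leader pass, materialized-bin calibration errors, pair-enumerated
AUC, finite differences for gradients and Hessians, dense-grid quadrature
for posterior moments (bounded at $\le 3$ parameters), and closed-form
paired t statistics.

Other numerical choices: probability clipping at $10^{-7}$; Newton
step-halving floor $10^{-10}$; Cholesky jitter $10^{-8}$; Monte Carlo
standard errors for sampler checks estimated from autocorrelation-based
effective sample sizes (squared samples for variance estimates, which mix
more slowly than the samples themselves).

## Known limitations

- The SMILES featurization path uses OpenBabel ECFP6 fingerprints, which
  fold natively to 4096 bits before placement in the requested bit space;
  hashed-collision statistics differ from 32k-bit implementations.
- HMC applies to the last layer only; full-network posteriors are out of
  scope by design (computationally impractical for routine use).
- Calibration errors are binned estimators: they inherit bin-count
  sensitivity, and a different $B$ changes the numbers (not the ranking of
  clearly separated methods).
- The synthetic generator's independence assumptions make its tasks easier
  to calibrate than real assay data under strong distribution shift;
  conclusions about *relative* method behaviour transfer, absolute scores
  do not.
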