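---
title: "Uncertainty-calibrated multimodal screening: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-calibrated multimodal screening: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parkscreen)
```

# The screening problem

Parkinson's disease produces signs across several modalities at once:
bradykinesia in fine motor control, hypomimia in facial expression, and
prosodic and articulatory changes in speech. Remote screening tools capture
short standardized task recordings — a finger-tapping task, a smile-mimicry
task, and a pangram utterance — and reduce each to a fixed-width tabular
feature block (130 motor features, 42 facial features, and a
1024-dimensional speech embedding). `parkscreen` implements the modeling
half of such a tool: per-task shallow classifiers with Monte-Carlo-dropout
uncertainty, an uncertainty-calibrated fusion network that combines the
three tasks, a withholding rule for unsafe predictions, demographic cohort
balancing for evaluation splits, and the statistics used to evaluate a
screening model as if it were a diagnostic test.

Because raw recordings of real participants are access-restricted, the
package ships a synthetic cohort generator that reproduces the *statistical
structure* the pipeline assumes. Everything downstream is developed and
tested against it.

# The synthetic cohort model

Each participant receives a latent severity

$$s \sim \mathcal N(+1, 1) \text{ (PD)}, \qquad
  s \sim \mathcal N(-1, 1) \text{ (non-PD)},$$

and each session of that participant uses $s_j = s + \varepsilon_j$,
$\varepsilon_j \sim \mathcal N(0, 0.25)$ (all normal distributions in this
document are parameterized as mean, sd). The shared $s$ induces
within-participant correlation across sessions, which is why splits must be
made by participant, never by session. For a modality with effect size
$\delta_m$ and $k_m$ informative coordinates, the first $k_m$ coordinates of
the block equal $\delta_m s_j$ plus $\mathcal N(0, \sigma_\text{noise})$
noise, and the remaining coordinates are pure noise. Task durations are
$\mathcal N(30\,\mathrm{s}, 5\,\mathrm{s})$ with occasional outliers planted
at mean $\pm 5$ SD to exercise the duration filter; modality blocks are
deleted independently at configurable rates (a session always keeps at
least one block); demographics (including explicit `unknown` levels) are
drawn from configurable subgroup proportions.

Default conditions mirror the population the generator emulates: 35.9% PD
prevalence, 52% female, ~11% non-white participants, ~31% of PD
participants with a recorded Hoehn–Yahr stage (stages are quantile bins of
severity among PD participants), and a modality signal ordering
speech > finger tapping > smile. Effect sizes default to 1.5 / 1.0 / 0.5
(speech / tapping / smile) with 64 / 20 / 10 informative coordinates — a
regime in which a well-trained fused model reaches an AUROC around 0.9
while single modalities trail it, matching the qualitative behavior the
pipeline is designed around.

What the generator deliberately does **not** model: feature covariance
within a block (real engineered features are correlated; here noise is
independent Gaussian), non-Gaussian tails, label noise in self-reported
status, and any drift between recording environments. Passing tests
therefore demonstrate correctness of the *pipeline mechanics* under the
stated latent model, not clinical performance on real recordings.

Reproducibility is structural: each participant's draws come from a child
RNG stream keyed by a stable hash of the participant ID, so insertion order
can never change a cohort, and one root seed reproduces the cohort
bit-for-bit.

# Preprocessing

*Duration filter.* A session's task is flagged when its duration deviates
from the task mean by more than three standard deviations, with mean and
sample SD ($n-1$) computed over all non-missing durations of that task in
the incoming table (not per split — the filter is a data-hygiene step, not
a modeling step). Flagged blocks are treated as missing downstream. With
equal durations (SD 0) nothing is flagged.

*Scaling.* Standardization or min-max scaling, fitted on training rows
only; constant columns map to 0.

*Correlation filter.* A greedy scan in file column order drops a column iff
its absolute Pearson correlation with an already-kept column exceeds the
threshold. Column order as tiebreak keeps the procedure deterministic
without inventing a ranking heuristic. Zero-variance columns correlate 0
with everything except an identical constant column already kept. The
threshold has no anchored default in the source protocol; the experiment
default is 0.98 (drop only near-duplicates).

*SMOTE.* Classic SMOTE only: synthetic minority rows are
$x + u (x_{nn} - x)$ with $u \sim U(0,1)$ and $x_{nn}$ among the $k$
nearest minority neighbors. Other oversampling variants are exposed in the
configuration enum as documented extension points but intentionally not
implemented: one fully tested implementation over several untested ones.

# Task models and Monte-Carlo dropout

Each task model is a shallow dense network (default one hidden layer, ReLU,
dropout after each hidden layer, sigmoid output) trained with binary
cross-entropy by SGD-with-momentum, AdamW, or RMSprop, with optional step
or reduce-on-plateau schedules. Dropout stays active at inference:
`mc_predict()` runs $T$ stochastic forward passes (default $T = 30$) and
summarizes each session's sigmoid outputs by their mean, sample SD, and the
empirical 2.5/97.5 percentile interval. The percentile convention (rather
than a normal approximation) is distribution-free; the per-pass samples are
retained on the prediction object so any other convention can be
recomputed after the fact.

The hyperparameter search is a seeded random search over the published
space (batch size {256, 512, 1024}; learning rate uniform on [5e-5, 1];
dropout uniform on [0.05, 0.5]; epochs uniform-integer on [1, 300]; three
optimizers; momentum [0.1, 1]; optional schedulers), selecting by
development-set AUROC of the MC mean probability. Trials that diverge
(non-finite loss — possible at the top of the published learning-rate
range) are logged and skipped. The default *experiment* configuration uses
a narrower, well-behaved slice of this space so small pipelines are stable;
the full space remains available via `task_search_space()` and
`fusion_search_space()`.

# The fusion network

Fusion operates only on complete sessions (all three blocks present).

1. **Projection.** Each preprocessed modality vector is mapped through
   linear → ReLU → MC dropout → layer normalization into a shared space
   (projection dimension from {128, 256, 512}). Layer normalization uses no
   affine parameters, so each projected row has mean 0 and variance 1 up to
   the normalizer's epsilon; an all-zero pre-normalization row maps to the
   zero vector.
2. **Uncertainty-calibrated attention.** Scaled dot-product self-attention
   over the three modality tokens, where the post-softmax weight toward key
   $j$ is multiplied by $e^{-\eta \sigma_j}$ and each row renormalized.
   $\sigma_j$ is the task-$j$ model's MC-dropout predictive SD on the
   probability scale, computed once per session and held fixed. The form is
   a design choice — the modulation is only qualitatively specified in the
   source protocol — picked because it is monotone in $\sigma_j$, reduces
   exactly to standard attention at $\eta = 0$ or equal sigmas, and spans
   meaningful behavior over the searched range $\eta \in [0.1, 100]$. It is
   isolated in one function and documented as swappable.
3. **Head.** The three contextualized vectors are concatenated with the
   three task-model mean probabilities (head input width
   $3P + 3$) and passed through one hidden layer with ReLU, dropout, and a
   sigmoid output; training is binary cross-entropy with analytic
   backpropagation through the whole stack (verified against finite
   differences in the test suite).

Task models are locked during fusion training: their probabilities and
sigmas enter as fixed inputs, and the fusion archive records content hashes
of the task-model weights so a fusion model cannot silently run against
retrained task models.

One practical subtlety deserves emphasis. With feature blocks wider than
the training set, a shallow task network separates its own training data
perfectly, so its *in-sample* probabilities are degenerate (essentially the
labels). A fusion head trained on those learns to copy the task
probabilities and inherits their optimism, and can end up *worse* than its
own inputs on held-out data — the classic stacking leak. `train_ufnet()`
therefore defaults to cross-fitted fusion inputs (`cross_fit_folds = 2`):
the probabilities and sigmas seen during fusion training come from task
models retrained on fold complements (folds assigned by participant), while
inference always uses the locked full models. Setting
`cross_fit_folds = 1` restores the literal in-sample protocol. Relatedly,
AdamW's decoupled weight decay is exposed (`weight_decay`, default 0.01)
because the high-dimensional blocks carry an essentially linear signal for
which strong L2 is the natural regularizer; larger values (0.1–0.5)
noticeably stabilize the fusion head.

*Why project raw (preprocessed) features rather than task-model hidden
activations?* The protocol describes both "integrating the outputs of the
task networks" and "projecting each task's features"; the latter is the
more specific statement, so projections consume the preprocessed feature
vectors and the task models contribute their mean probabilities to the
head. This also keeps the task models' uncertainty role cleanly separated
from their representation role.

# Withholding (selective prediction)

`fuse_predict()` reports a fused MC summary per session; `decide()` issues
`positive` / `negative` by comparing the MC mean to the decision threshold
(default 0.5, exposed because deployment contexts weight sensitivity and
precision differently), and **withholds** whenever the percentile interval
contains the threshold — the interval then spans both classes and the model
declines to issue a verdict. Withheld sessions are excluded from
confusion-matrix metrics and reported as a coverage rate (the fraction of
sessions receiving a verdict); how withheld cases entered the source
protocol's own metrics is unstated, and excluding-plus-reporting is the
transparent option. Because percentile intervals are nested in the level,
coverage is monotone nonincreasing as the interval level rises — this, and
the property that retained-session accuracy is at least full-set accuracy
on average, are both checked in the acceptance suite.

# Cohort balancing and splits

Evaluation cohorts are balanced demographically by a genetic algorithm
minimizing the diversity loss

$$\mathcal L = \sum_{a \in C} \sum_{i \in a} \frac{(E_i - O_i)^2}{E_i},$$

over attributes $C$ = {sex, ethnicity, age bin} with expected counts $E_i$
from target proportions (defaults: sex 50/50; ethnicity 45/45/10 with an
explicit `unknown` subgroup; age below-50/at-or-above-50/unknown 45/45/10).
Each restart begins from a random selection with exact class counts (PD
balance is held exact by construction, so PD status is not a scored
attribute), proposes one same-class swap per iteration, and accepts it only
on a *strict* loss decrease (so equal-loss swaps cannot cycle). The source
protocol gives no stopping criterion beyond "converges to a local optimum";
a restart here stops after `max_stale` (default 2000) consecutive
rejections — a bounded-runtime convergence proxy — and the best of
`restarts` (default 500) restarts wins. Subgroup levels not named in the
targets (e.g. unknown sex under a 50/50 sex target) fall into unscored sink
bins: a populated subgroup with expected proportion literally 0 is a
configuration error, but levels outside the target scheme simply do not
contribute. Test cohorts are selected first, removed, and the development
cohort selected from the remainder, so no participant appears in two
splits. On pools small enough to enumerate, the GA provably reaches the
exhaustive-search optimum (checked in the acceptance suite).

# Evaluation suite

Session-level evaluation (the natural unit for a screening encounter) with:
confusion metrics that report undefined ratios as missing rather than 0;
AUROC via the rank/Mann–Whitney identity with half-credit ties; AUPRC by
step integration; Brier score; ECE over 10 equal-width bins (the bin count
is not anchored by the source protocol; 10 is the common convention) with
empty bins skipped; percentile bootstrap intervals (B = 1000) whose
resample distributions feed Mann–Whitney comparisons between models;
two-proportion pooled z-tests that *refuse* when $np \ge 5$ fails rather
than silently falling back; Monte-Carlo chi-square with fixed margins and
the add-one p estimator (p is never 0); Benjamini–Hochberg adjustment;
Cohen's kappa with an explicit not-available result when both raters are
constant and equal; odd-panel majority votes; a logistic misclassification
regression (IRLS) that refuses on separation; and the eight-region
decomposition of fused accuracy by which task models were correct.
Percentile bootstrap (not BCa) matches the stated resampling protocol and
keeps the resample distribution directly interpretable.

# Numerical choices

* Layer-norm epsilon $10^{-6}$; degenerate all-zero rows pass through as
  zeros rather than exploding.
* Dropout is "inverted" (masks scaled by $1/(1-p)$) so expectations match
  between training and deterministic inference.
* BCE probabilities are clipped to $[10^{-12}, 1-10^{-12}]$.
* Sample statistics use the $n-1$ denominator throughout; the GA accepts
  only decreases larger than $10^{-12}$ to keep float noise from cycling.
* He initialization for all dense layers; every training routine seeds
  initialization, shuffling, and dropout from its spec seed, and restores
  the caller's RNG state afterwards.

# Problem sizes used by the tests and the acceptance script

The test suite exercises the pipeline at deliberately modest scales chosen
as the package's own defaults for desk-scale verification: cohorts of
120–1200 participants, 800 fusion training sessions (single-session
participants) with 400 held-out participants for the fusion-recovery
property, 500 held-out sessions for the withholding property (5 seeds
each), 500 bootstrap-coverage replications at B = 1000, and GA runs with
up to 500 restarts. `scripts/acceptance.R` runs
the full pipeline on a 400-participant synthetic cohort with GA-balanced
splits (80 test / 50 development), a budget of 3 per search, and B = 1000
bootstrap intervals, then writes the principal quantities (accuracy,
sensitivity/specificity, AUROC/AUPRC, Brier, ECE, coverage, agreement with
truth, GA loss) as JSON.

# Known limitations

* The fusion model cannot handle sessions with missing blocks; extending
  attention to variable token sets is future work.
* No post-hoc probability recalibration (temperature or Platt scaling) is
  applied; calibration is measured, not corrected.
* The independent-Gaussian feature model understates the redundancy of real
  engineered features; absolute AUROC values on synthetic cohorts should
  not be read as clinical estimates.
* The GA optimizes a single diversity objective; multi-objective or
  proportion-optimizing variants are out of scope.
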