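---
title: "Two-phase neural architecture search for MWR risk classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase neural architecture search for MWR risk classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Medical microwave radiometry (MWR) records internal tissue temperature at
3–5 cm depth by measuring naturally emitted thermal radiation. For breast
screening, 44 temperatures are taken per patient: on each gland the nipple,
eight surrounding points and an axillary point, each on the skin surface
and at depth, plus two reference points below the chest. Tumour metabolism
raises local temperature, so high-risk patients tend to show localized,
*unilateral* depth-temperature excesses, while healthy tissue is close to
left/right symmetric. The package classifies a patient's 44-value profile
as low or high risk.

## Phase 1: weight-agnostic topology search

A classifier here is a feedforward DAG *genome*: typed nodes (44 inputs, a
constant-1 bias, hidden nodes, one sigmoid output) and enable-flagged
weighted connections. The search evaluates *architectures, not weights*:
a single shared scalar is substituted into every connection, the network is
run over the training rows, outputs are thresholded at 0.5, and the G-mean
`sqrt(sensitivity * specificity)` is recorded for each shared weight in
{−2, −1.5, −1, −0.5, +0.5, +1, +1.5, +2}. A topology that scores well
across many shared weights encodes its discriminative power in its wiring —
an inductive bias — rather than in tuned parameters.

Populations (default 200 genomes, 200 generations; `wann_config()`) start
minimal: no hidden nodes, each possible input/bias→output connection
enabled with probability 0.2. Offspring receive exactly one of three
mutations — change a hidden node's activation (p = 0.5), insert a node by
splitting an enabled connection (p = 0.25; the split edge is disabled, so
the enabled count rises by one and lineage information is preserved), or
add a connection between a uniformly chosen valid pair that keeps the graph
acyclic (p = 0.25). When the sampled operator cannot apply, the fallback
order is add-connection, change-activation, add-node, identity. Mutations
only ever grow the network; there is no deletion or crossover.

Hidden activations come from an 11-function pool (linear, binary step, sin,
cosine, sigmoid, Gaussian `exp(-x^2)`, tanh, inverse `-x`, absolute value,
ReLU, squared). The output node is fixed to the logistic sigmoid and
excluded from activation mutation: downstream weight training minimizes
cross-entropy and reports 0.5-thresholded classes, both of which presuppose
a probability output.

Ranking is NSGA-II on three simultaneous objectives: maximize the mean
G-mean over the shared weights, maximize the best single-weight G-mean,
and minimize the enabled-connection count. Parents are drawn by size-4
tournaments (lowest front wins; ties broken by larger crowding distance,
then lower population index), and the first front is carried over unmutated
(capped at 20% of the population). The best genome overall is the front-0
member with the highest *validation* mean G-mean, ties broken by fewer
connections.

## Phase 2: BIPOP-CMA-ES weight training

With the topology frozen, its weight vector (one entry per enabled
connection) is optimized against training cross-entropy by CMA-ES with the
standard strategy constants: weighted recombination of the best half of
each generation, cumulative step-size adaptation, and rank-one plus rank-μ
covariance updates. The start point sets every slot to the best single
shared weight found by a 41-point linear scan of [−2, 2] (step 0.1; ties
prefer the smallest |w|, then the smallest w). Restarts double the
population from λ = 50 (50, 100, 200, …), re-centre on the incumbent best
and reset the covariance; a restart ends after 50 generations without
improvement of the best objective value. Model selection is a running
minimum of *validation* cross-entropy over every candidate evaluated,
so the returned weights can never be worse on validation than the scanned
shared-weight start, which is evaluated first.

Numerical safeguards: pre-activations are clamped to [−10⁴, 10⁴] before
activation (squared and inverse activations otherwise overflow on
unconstrained random topologies); probabilities are clipped to
[10⁻¹², 1 − 10⁻¹²] inside the cross-entropy; the optimizer stops a run when
the covariance condition number exceeds 10¹⁴ or the step size degenerates,
and reports which of budget/stagnation/degeneracy ended it. The covariance
is re-symmetrized every generation and its eigenvalues checked positive.

## The cascade-correlation baseline

The CCNN starts as a logistic unit over the 44 inputs and grows one hidden
unit per iteration: a pool of 30 sigmoid candidates (weights ~ N(0, 0.5²),
zero bias, batch-normalized, dropout 0.5 during training only) is trained
by gradient ascent on the magnitude of the centered covariance between
candidate output and the current *residual* error; the best candidate on
the validation residuals is frozen (weights and normalization statistics)
and wired into the network, the output layer is reinitialized and retrained
with cross-entropy, and the loop stops after five iterations without
validation-loss improvement. Correlating with residuals rather than the raw
target is deliberate: every unit after the first would otherwise chase the
same signal. Batch-normalization statistics freeze with the unit; dropout
is disabled at inference. The default learning rate (5 × 10⁻⁶) follows the
reference protocol for the 44-feature clinical task; the two-feature XOR
demonstrations in the tests pass 0.5 through the same configuration field
because all losses and score gradients in this implementation are
mean-scaled, and a toy task at that scale needs a proportionally larger
step.

## Data handling

The loader maps delimited text onto the canonical 44-column schema
(`l0_skin` … `t2_depth`), translates textual labels, and drops rows with
missing or unparseable cells, reporting the count. Class balancing
undersamples the majority class to the minority count — it keeps only real
measurements and matches the reported balanced protocol — and happens
*before* the stratified 60/20/20 train/validation/test split (per-class
sizes within one row of exact). The experiment pipeline additionally
standardizes every feature column by the training partition's mean and
standard deviation: raw temperatures sit at 33–36 °C, so order-one shared
weights would otherwise saturate the output sigmoid and score every genome
at G-mean 0. Test rows are transformed with training statistics only and
reach the models exactly once, at final evaluation.

## The synthetic generator

`generate_synthetic_mwr()` emulates the structural features the method
exploits: per-position Gaussian measurement noise (sd 0.4 °C) *shared*
between the glands, so healthy left/right pairs are strongly coupled; an
independent per-side term scaled so the left-minus-right difference has
sd 0.15 °C; skin around 33.5 °C and depth around 36.5 °C; and, for
high-risk rows only, a hotspot of +1.5 °C on three contiguous depth
positions of one random gland with half that excess on the overlying skin.
A threshold on the maximum left-right depth gap separates the default
classes nearly perfectly, so the task is solvable in principle by a small
network with a sign-invariant unit.

What the generator does *not* emulate: device calibration drift,
age/physiology covariates, inter-clinic protocol differences, label noise
from the clinical composite ground truth, and the 4377:535 prevalence of
the real data (configurable but defaulting to balanced classes for the
pipeline demonstrations). Passing tests on synthetic data therefore
demonstrate correctness and internal consistency of the algorithms, not
clinical performance.

## Behaviour at reduced scale

The tests and the acceptance script run the search at population 64 for 30
generations with a 2000-evaluation training budget, for runtime reasons
stated here as the package's demonstration scale. This is a 10×-smaller
search than the full protocol, and it changes what phase 2 can deliver.
The ideal solution — an absolute-value (or other even) hidden unit fed by
left and right depth columns, whose weights CMA-ES can sign oppositely to
detect asymmetry — trains to F1 ≈ 0.98 when built by hand. But
shared-weight evaluation cannot reward evenness (all weights carry the same
sign), so at small population-generation budgets the evolved hidden units
are mostly odd or monotone activations and the topology's trainable ceiling
sits near F1 0.8 regardless of optimizer budget. Weight training still
reduces validation cross-entropy markedly and the four weight schemes order
as expected on average (random ≤ fixed shared ≤ tuned shared ≤ trained),
but single-seed thresholded F1 margins between the tuned shared weight and
full training are small and can invert. At the full published scale the
search has roughly 40× more mutation events to discover sign-invariant
structure, which is consistent with the large training gains reported
there.

## Other design choices

- **Three simultaneous objectives.** The classic weight-agnostic search
  alternates two-objective rankings; this implementation ranks on all three
  criteria simultaneously, matching the protocol it reproduces. Its known
  side effect —
  ultra-sparse, low-performance genomes persisting on front 0 — is damped
  by crowding-ordered elitism but not removed.
- **Hidden nodes with no enabled inputs** emit `activation(0)` instead of
  being pruned, so mutation can never produce an unevaluable genome.
- **Duplicates are permitted** in the population (no structural hashing);
  deduplication would change the search dynamics.
- **Tie-breaks are everywhere deterministic** (node-id order in the
  topological sort, |w| in the weight scan, fewer connections for equal
  validation scores), so a fixed seed reproduces every artifact bit for
  bit.
- **Paired model comparison** uses a two-sided paired t-test on per-sample
  absolute errors over the shared test rows, plus the mean ± sd of absolute
  element-wise output differences; standard deviations use the n−1
  denominator throughout.
- **Serialization** writes JSON with 17 significant digits, which
  round-trips IEEE doubles exactly.

## Known limitations

Single-output binary classification only; no recurrent or convolutional
structure; no crossover, deletion or speciation operators; the restart
schedule implements the doubling (large-population) regime only, without
the canonical alternating small-population budget; gradient-based weight
training is intentionally absent. Clinical use would require validation on
real MWR data at full search scale.
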