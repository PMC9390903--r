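---
title: "Methods: the ridge-screened Q-learning bee swarm selection cascade"
author: "rqbso package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ridge-screened Q-learning bee swarm selection cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rqbso)
```

## The problem

Clinical cohorts used for risk prediction — the motivating case is neonatal
necrotizing enterocolitis, a few hundred patients described by on the order
of a hundred mixed binary/continuous variables — combine three difficulties:
missing entries scattered across most columns, class imbalance around 2:1,
and far more candidate predictors than a small parsimonious model needs.
`rqbso()` addresses them with a fixed cascade: sparsity filtering, hybrid
k-nearest-neighbour imputation, z-score normalisation, an embedded ridge
pre-screen, and a wrapper search over feature subsets driven by a
Q-learning-guided bee swarm, scored by cross-validated linear-SVM accuracy.

This vignette explains each stage's model and assumptions, the tunable
parameters, the places where the procedure was genuinely open and how the
package decided them, and what the synthetic validation does and does not
establish.

## Preprocessing

**Sparsity rule.** A column is removed iff its missing proportion is
*strictly greater than* `missing_drop_fraction` (default 0.30). The
boundary case — exactly 30% missing — is retained.

**Hybrid k-NN imputation.** For a missing cell $(a, i)$, every row $b$ that
observes column $i$ is a candidate donor. The similarity weight is the
reciprocal Euclidean distance over the features observed in *both* rows
(the target column is never among them, being missing in row $a$); discrete
features contribute a 0/1 mismatch term. Continuous targets are filled with
the weight-averaged donor values — a convex combination, so fills always
lie inside the donors' range — and discrete targets with the modal category
of the $k$ nearest donors. Three points were open and are fixed as follows:

* *Zero distance.* An identical donor makes the reciprocal weight undefined;
  distances are floored at $10^{-12}$, so exact duplicates dominate the fill
  without dividing by zero.
* *Mode ties.* Tied categories are resolved toward the candidate with the
  smallest summed donor distance, then by category order; this keeps the
  fill deterministic.
* *Fill order.* All fills are computed from the original observed values and
  written at once. Chained imputation would make results depend on row
  order; this way the operation is order-free and idempotent, both of which
  the test suite checks.

`knn_k` defaults to 5 — the field's customary neighbourhood for small
cohorts; the value is deliberately explicit and configurable because no
single default suits every missingness pattern.

**Normalisation.** Continuous columns are centred and divided by their
population (divide-by-$n$) standard deviation; the convention matters only
for exact reproducibility and is stated for that reason. Binary/categorical
columns are left untouched: z-scoring category codes has no meaning. A
constant column gets scale 1 with a warning rather than a division by zero.
The stored centre/scale pair lets `predict()` apply the identical transform
to new samples.

## Ridge pre-screening

The 0/1 class label is treated as a regression target and fitted with the
penalised least-squares objective
$J(\beta) = \sum_i (y_i - \beta^\top x_i)^2 + \lambda\lVert\beta\rVert_2^2$,
whose minimiser solves $(X^\top X + \lambda I)\beta = X^\top y$. The system
is solved by Cholesky factorisation of the penalised Gram matrix — the
contract is the normal equations, not a literal matrix inverse. $\lambda$
is selected from a grid of 50 log-spaced values spanning $10^{-2}$ to
$10^4$ by k-fold cross-validated held-out squared error (ties to the
smaller penalty). The wide default grid brackets the strong penalties such
imbalanced label regressions typically select.

Penalised coefficients are almost never exactly zero, so "remove
zero-coefficient features" is implemented as a threshold: feature $j$
survives iff $|\beta_j| > \varepsilon$, with
$\varepsilon = 10^{-6}\max_j|\beta_j|$ by default. The intent — discard
clearly irrelevant columns to shrink the wrapper's search space — is kept
while staying mathematically well-posed; screening is monotone in
$\varepsilon$ and errors out rather than returning an empty feature set.

## The QBSO wrapper search

States are bit masks over the screened features; the action is flipping one
bit.

**Search areas.** Each round derives `flip` candidate solutions per
strategy from the reference solution. Strategy 1 flips interleaved bits
$\{k, k+\mathrm{flip}, k+2\cdot\mathrm{flip},\dots\}$; strategy 2 flips
contiguous blocks of $\lfloor n/\mathrm{flip}\rfloor$ bits, the last block
absorbing any remainder when `flip` does not divide $n$. For divisible $n$
both strategies' flipped sets partition the bit positions, which the tests
verify against the 20-bit, flip-5 worked example. Bees alternate between
the two strategies; if more bees are requested than the $2\cdot\mathrm{flip}$
available candidates, further candidates are generated on a freshly
permuted bit order so extra bees explore genuinely different areas.

**Local search.** Each bee repeats `local_iteration` times: enumerate all
single-bit-flip neighbours (a flip that would empty the mask is skipped),
score each neighbour's reward against the current state, update the Q entry
of the (state, flipped-bit) pair as $Q \leftarrow r + \gamma Q$ with the
table zero-initialised, then move greedily to the neighbour with the
largest updated Q, ties to the lowest bit index. The reward prefers
accuracy first and parsimony second: an improvement earns the new accuracy,
a deterioration the (negative) difference, and at exactly equal accuracy
the move earns $\pm\tfrac12$ the new accuracy by whether the subset shrank
or grew. Equal accuracy *and* equal size — a case the strict branches do
not cover — earns 0.

**Rounds and diversification.** The bee achieving the round's largest
updated Q value seeds the next reference solution; if a round's maximum Q
falls below the previous round's, the next round restarts from a fresh
random 20% subset instead. The best-*fitness* solution ever visited is
tracked separately and returned, so the recorded best fitness is
non-decreasing even across diversification restarts. Several aspects of
this bookkeeping were open:

* One shared Q-table serves all bees (the structure diagram of the method
  shows a single table); sharing lets later bees exploit earlier bees'
  updates within a round.
* "The round's maximum Q" for the diversification trigger is the largest
  updated Q observed across the round's local searches.
* Greedy neighbour choice with a lowest-index tie rule, rather than
  ε-exploration: the method description selects "the subset with the
  largest Q value", and determinism requires a tie rule.

Fitness values are memoised by mask: the search revisits states constantly,
results are unchanged, and the cost drops severalfold.

**Defaults.** `flip = 5`, `n_bees = 10`, `max_iteration = 10`,
`local_iteration = 10`, `gamma = 0.1`, `init_fraction = 0.2` — the
reference settings of the search — and `svm_C = 1`, `fitness_folds = 10`.
$\gamma$ discounts the stored value when a pair is revisited; with rewards
bounded by 1 all Q values stay within $1/(1-\gamma)$.

## Fitness, evaluation and the SVM

Subset fitness is the mean held-out accuracy of a linear SVM over
stratified k-fold cross-validation. Stratification (the folds preserve the
class mix) is used because unstratified folds can lose the minority class
entirely on imbalanced cohorts; the assignment depends only on the labels
and a seed — never on the mask — so all subsets are compared on identical
splits.

The SVM is the package's own dual coordinate-descent solver for the
hinge-loss linear SVM (soft margin, penalty `C`), with the customary
shrinking heuristic and a penalised unit-bias intercept, built in compiled
code because the wrapper loop needs hundreds of thousands of small fits per
selection run. The dual tolerance is 0.1, the customary stopping point for
this solver family; the test suite bounds the disagreement of held-out
accuracies against a reference libsvm-based implementation, with observed
differences small and in both directions. Fits are deterministic: a
private generator drives the coordinate ordering and R's RNG stream is
never touched.

The final subset is re-evaluated under a fold seed distinct from the one
the search optimised, pooling held-out predictions into confusion counts
(ratios with zero denominators are reported as 0 and flagged), and pooling
held-out decision values into ROC and precision–recall curves — AUROC by
the trapezoid rule with tied scores grouped, AUPRC by step interpolation.
Decision values rather than hard labels feed the sweep; a hard-label
classifier would yield a single ROC point. Using a distinct seed documents,
but does not remove, the leakage inherent in selecting and evaluating on
the same samples: the held-out report is still optimistically biased, and
an honest external estimate would need a nested protocol on fresh data.

`importance_ranking()` re-runs the whole selection under derived seeds and
scores each feature by its selection frequency weighted by the run's final
fitness, normalised to sum 1. It is a stability summary of a stochastic
search, not a model-based importance measure, and is labelled accordingly.

## Seeding

One master seed deterministically spawns the per-stage seeds (ridge CV
folds, fitness folds, search randomness, final evaluation folds), so a fit
is byte-reproducible from `(dataset, arguments, seed)`. All stochastic
package functions restore the caller's RNG state.

## The synthetic cohort generator

`simulate_clinical()` emulates the target cohort shape: default 447 samples
by 119 variables, positive fraction 296/447, half binary and half
continuous columns, missingness 10% completely at random, ten planted
informative features each with one redundant partner correlated at 0.5.
Continuous informative columns shift their class mean by `effect_size`
standard deviations; binary informative columns shift their log-odds by
`effect_size` around a baseline prevalence of 0.35. Continuous partners are
noisy copies at the requested correlation; binary partners are random flips
with matching agreement. The defaults were chosen once as a realistic
clinical mix and are not tuned per experiment.

Note an asymmetry built into the effect definition: a 1.5 log-odds shift in
a binary flag carries roughly half the discriminative signal of a 1.5 SD
shift in a continuous measurement. Weak binary signals can therefore be
*correctly* excluded by an accuracy-maximising wrapper — the cross-validated
fitness of a mask without them can exceed that of the planted truth —
especially when a correlated partner carries most of the same information.
Recovery experiments on mixed cohorts must be read with that in mind: a
dropped weak binary feature is the method optimising its stated objective,
not a search failure.

What the generator does **not** emulate: the real cohort's covariance
structure beyond pairwise partner correlation, informative missingness
(everything is MCAR), non-linear or interaction effects, measurement drift,
and calibration between centres. Passing the synthetic suites therefore
shows the machinery is implemented correctly and behaves as designed under
known ground truth — not that the selected variables from any particular
clinical dataset are biologically meaningful.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle at sizes
chosen to keep the full run comfortably fast while exercising every code
path: brute-force re-evaluation of the imputation definitions on 50 random
tables up to 8×6; a restarted BFGS minimiser of the ridge objective on 50
random instances up to 20×10 (agreement to $10^{-8}$, plus monotone
shrinkage); an independent step-by-step re-simulation of the swarm's
method's stated rules on 3–4-bit problems with exhaustively tabulated fitness;
metric identities against the Mann–Whitney rank statistic and a reference
ROC implementation; and a 10-seed planted-recovery study at 200×30 with
five informative features at effect 1.5 under the full default search.

## Known limitations

* The wrapper's fitness and the final report share the same samples;
  reported metrics are optimistic (see above).
* The reward's parsimony branch makes the search actively drop features
  that do not change cross-validated accuracy, which trims redundant
  predictors but can also discard weak true signals on small cohorts.
* The ridge screen is linear; a feature informative only through
  interactions can be screened out before the wrapper ever sees it.
* No comparison selectors or alternative classifiers are bundled; the
  package implements one method well rather than a benchmark harness.
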