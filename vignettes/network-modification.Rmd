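---
title: "Treating maladaptive behavior by network modification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Treating maladaptive behavior by network modification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmod)
```

## The model organism and its task

`netmod` studies a deliberately minimal "model organism": a 4-3-4
feedforward neural network whose inputs are four binary cues — immediate
danger, food availability, alcohol availability, and consumption risk — and
whose four softmax outputs are the actions escape, eat, drink and wait.
Hidden ("processing") node activity is `tanh(w1 %*% x + b1)`; output
activity is `softmax(w2 %*% h + b2)`; the selected action is the output
argmax (ties, which have probability zero under input noise, break toward
the lowest action index).  The 31 parameters — 12 input weights, 12 output
weights, 3 hidden biases, 4 output biases — are indexed by a canonical flat
ordering in which **parameter 12** is the weight from the consumption-risk
input to processing node 3 ("CoR3").

A trial presents one of six cue patterns with i.i.d. Gaussian noise
(sd 0.2) added per channel; noisy inputs are deliberately *not* clipped,
since the noise model is purely additive.  Five patterns have
uncontroversial targets (danger→escape, food→eat, alcohol→drink,
food+risk→wait, and alcohol+risk under *aversion-sensitive* rules→wait).
*Aversion-resistant* rules differ on exactly one pattern: alcohol+risk→
drink, the maladaptive behavior under study.  The sixth pattern is taken to
be the all-cues-off trial with target wait: the remaining five are fixed by
the task description, and waiting is the only neutral action for a
stimulus-free trial.

Two behavioral metrics summarize a network under aversion-sensitive
targets: the **aversion-resistant drinking rate** (fraction of alcohol+risk
trials answered with drink) and the **side-effect rate** (error rate on the
other five trial types).  Their sum is the total error used as the
treatment objective.  The side-effect denominator is per-category
(non-alcohol+risk trials) so that a perfect aversion-resistant network
scores drinking ≈ 1; the all-trials convention is available via
`evaluate_network(..., side_effects = "all_trials")`.

## Training and the population conditions

Populations are built by training randomly initialized networks
(i.i.d. uniform on [-1, 1]) on 1000 noisy trials and accepting a network
only if its error on a fresh held-out 1000-trial batch is below 5%;
rejected attempts are retried from new seeds.  Retrained networks start
from an accepted aversion-resistant parent and are fitted to the
aversion-sensitive rules, keeping the parent's identifier so treatments can
be compared within lineages.

Each training attempt draws a random configuration from a small family of
optimizers: Adam (learning rate log-uniform on [0.005, 0.2]),
gradient descent with momentum 0.9 (rate log-uniform on [0.05, 0.5]), or
resilient backpropagation (sign-based adaptive steps), each stopping once
the training-batch error falls below a threshold drawn uniformly from
[1%, 4.5%] (budget 3000 epochs).  This heterogeneity is a deliberate part
of the study conditions, standing in for training with one of several
randomly selected algorithms: a single optimizer configuration produces an
unrealistically uniform population in which every network is rescuable by
a single-parameter treatment, whereas the phenomena of interest include
the small subpopulation that resists such treatment.  All losses are
softmax cross-entropy; accuracy is always measured on the argmax actions,
not the loss.

## Characterization

**Encoding.**  Node activity over the test batch is discretized into four
equal-count bins (rank-based; ties go to the lower bin, remainders to the
earliest bins).  The encoding of cue *j* is the interaction-corrected,
entropy-normalized mutual information
`[I(X; all cues) − I(X; cues except j)] / H(X)` — the difference removes
cue-cue interactions; the plug-in estimator (log base 2) is used
throughout, so small negative input encodings can occur within estimator
bias and are left visible rather than clipped.  Output encodings use the
one-hot indicator of each action, `I(X; action = j) / H(X)`, because the
softmax makes actions mutually exclusive.  Constant-activity nodes are
reported as degenerate with all encodings zero.

**Relabeling.**  Because hidden-node roles land in random positions during
training, every population is renumbered before comparison: the 8-value
encoding profiles of all nodes of all networks of one population are
reduced to two principal components (centered, not variance-scaled — the
encodings already share a [0, 1] scale), clustered by k-means (3 clusters,
10 restarts, seeded), and each network's three nodes are matched
bijectively to the clusters by the minimum-total-distance permutation in
PC space.  The cluster with the highest mean escape-output encoding
becomes node 1, then eat → node 2, and the remainder → node 3.  Weight
rows/columns and biases are permuted together, so relabeling never changes
any network's input-output function (a property the tests verify
directly).

**Comparison.**  Parameter and mean-activity distributions of the
aversion-resistant and aversion-sensitive populations are compared with
two-sample KS statistics.  The 24 connection weights are compared on
absolute values — collapsing excitatory and inhibitory solutions that are
behaviorally equivalent — while the 7 biases keep their sign; the rule is
overridable (`abs_params`).  The descending-KS rankings of the 31
parameters and the 18 (node × trial type) mean activities supply the
predictor subsets for treatment prediction.

## Treatment

**Retraining imposition.**  The 31 parameter changes between an
aversion-resistant network and its retrained version are imposed
cumulatively from largest to smallest magnitude, tracing a 32-point curve
from untreated to fully retrained.

**Random search.**  The treatment search is a derivative-free iterative
Gaussian search: 100 proposals per iteration around the current value
(initial sd 10; thereafter `min(0.5, |previous − new|)` per coordinate),
keep the best, stop when the relative improvement drops below 1% (or the
objective hits zero).  Three numerical choices close gaps the procedure
leaves open: the sd update uses the absolute move; a no-move iteration
drops the sd to a floor of 0.01 for one extra iteration before the
stopping rule fires (avoiding degenerate zero-sd proposals); and the
current value is always included as a 101st candidate, which makes the
search monotone and never worse than baseline.  Within one network's
search the objective is evaluated on a fixed, seeded batch so the
optimization is deterministic; the reported ("achieved") metrics always
come from an independent fresh batch.  Pair searches draw 100 candidate
*pairs* with the same schedule applied per coordinate.  Single- and
two-parameter changes perturb the output logits by at most two rank-one
terms, which is what makes evaluating 101 candidates per iteration cheap;
the bulk evaluator is tested for exact agreement with the naive forward
pass.

**Failure.**  A treated network fails if its achieved aversion-resistant
drinking rate exceeds 0.1.  Networks that fail the exhaustive
single-parameter search are escalated to the exhaustive two-parameter
search.

## Treatment prediction

Both prediction protocols are leave-one-out PLS regressions over the
aversion-resistant population: the held-out network contributes no rows to
the fit.  Protocol 1 predicts the searched CoR3 value from either all 31
parameters, all 18 activities, top-*l* KS-ranked subsets (*l* = 1..6,
rankings computed once from the full population comparison), or random
size-*l* subsets; the prediction is imposed on parameter 12 alone and
evaluated fresh.  Protocol 2 predicts all 31 searched values plus their 31
achieved total errors (62 responses), tests the 8 candidates with the
lowest *predicted* error on the actual network, and keeps the tested
candidate with the lowest realized error.

PLS is fitted by SIMPLS with predictors and responses standardized to zero
mean and unit variance (constant columns centered only) and predictions
de-standardized; the component count defaults to `min(p, 5)`, which keeps
the single-predictor protocols well-posed while saturating the 31-column
case, and is reduced automatically (with a warning) on rank-deficient
problems.

## Reproducibility and problem sizes

Every random draw flows from a sub-seed derived by hashing a master seed
with stage and network labels, so any stage can be re-run in isolation and
identical configurations give bit-identical artifacts.  The package's own
test suite exercises the population-level claims at reduced sizes chosen
to keep a complete run comfortable on one CPU: 200 aversion-resistant and
100 aversion-sensitive networks (100 retrained lineages) with full
31-parameter searches, versus 1000 per population in the original study
design; `scripts/acceptance.R` re-derives the headline statistics from
scratch at 200 networks.  Batch sizes stay at the study's 1000 trials.

## What the generator does and does not emulate

The synthetic populations reproduce the study conditions — six trial
types, additive input noise, the 5% acceptance criterion, optimizer
heterogeneity — but they remain small abstract networks: no temporal
structure, learning during test, pharmacology, recurrence, or biological
connectivity.  Passing population-level checks therefore demonstrates that
the analysis and treatment machinery behaves as described on networks of
this class, not that the conclusions transfer to biological circuits.
Known limitations worth keeping in mind: functional relabeling is
imperfect for networks whose solution distributes drinking across nodes
(these networks are also where non-CoR3 treatments win); plug-in MI is
biased upward at small samples (the estimator is kept deliberately simple,
with no bias correction);
and KS-based predictor rankings are population-level, so they can be
suboptimal for atypical individuals.
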