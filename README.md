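# netmod

Treating maladaptive behavior by modifying the parameters of the neural
network that produces it — in a population of simple model organisms.

## The problem

A recurring idea in computational psychiatry is that the maladaptive
behaviors characterizing neuropsychiatric disorders (here: aversion-
resistant alcohol drinking, a hallmark of alcohol use disorder) are most
proximally produced by a network of neurons, so treatment can be recast as
*network modification*: which parameter(s) of an individual's network
should change, and to what value, to remove the maladaptive behavior
without side effects?  `netmod` implements a complete test bed for this
program on the smallest network that supports it.

Each model organism is a 4-3-4 feedforward network: four binary cues
(danger, food, alcohol, consumption risk) with additive Gaussian noise
(sd 0.2), three `tanh` "processing" nodes, four softmax outputs (escape,
eat, drink, wait) whose argmax is the behavior,

```
x_hidden = tanh(w1 %*% x_in + b1)
x_out    = softmax(w2 %*% x_hidden + b2)
```

31 parameters in all.  Aversion-resistant and aversion-sensitive
populations are trained to < 5% error on rule sets that differ only on
alcohol+risk trials (drink vs wait).  The package then provides:

- **Characterization** — node silencing (ablation), entropy-normalized
  mutual-information encoding of cues and actions with an interaction
  correction, functional node relabeling (PCA + k-means over encoding
  profiles), and Kolmogorov–Smirnov comparison of parameter and activity
  distributions between populations.
- **Treatment** — full retraining; cumulative imposition of retraining
  changes ordered by magnitude; and a derivative-free iterative Gaussian
  random search over single parameters and parameter pairs (100 proposals
  per iteration, initial sd 10, adaptive sd capped at 0.5, 1% relative
  stopping rule) minimizing drinking-plus-side-effect error.
- **Prediction** — leave-one-out partial-least-squares models that predict
  effective parameter modifications for an unseen network from its
  parameters or its mean node activities, including top-*l* KS-ranked and
  random predictor subsets.

The headline phenomena this machinery reproduces: one parameter — the
consumption-risk → processing-node-3 weight, "CoR3", flat index 12 — is the
best single-parameter treatment for the large majority of networks; a
small fraction of networks resists every single-parameter treatment but is
rescued by two-parameter search; and node *activity* predicts successful
treatment better than network *structure* when little information is
available.

## A worked example

```r
library(netmod)

pops <- build_populations(10, master_seed = 5)
batch <- generate_trials(1000, "aversion_sensitive", seed = 99)

# an aversion-resistant network drinks on alcohol+risk trials
evaluate_network(pops$ar$networks[[4]], batch)
#> <behavior_metrics> AR drinking 0.994 | side effects 0.029 | total 1.023

# relabel nodes by functional role, then search all 31 parameters
ar  <- relabel_nodes(pops$ar, batch, seed = 1)
sa  <- search_all_params(ar$networks[[4]], batch, seed = 1)
sa$best
#> <treatment_record> ar-0004: param(s) 12 -> 2.779 | achieved AR drinking 0.0174
```

The treated network stops drinking on alcohol+risk trials (rate 0.994 →
0.017) by changing only parameter 12 (CoR3), while the side-effect rate
stays at the trained level.  (Not every network is treated through CoR3 —
a minority of solutions route drinking through another processing node and
get a different best parameter; at population scale CoR3 dominates.)  `compare_populations()` shows the same parameter has
the most separated distribution between aversion-resistant and
aversion-sensitive populations, and `predict_cor3_treatment()` /
`predict_best_treatment()` reproduce such treatments for held-out networks
without running a search on them.

A thin command-line wrapper over these functions is installed at
`inst/cli/netmod.R` (`train`, `retrain`, `treat`, `pipeline`), and
`run_pipeline()` writes a full artifact directory (JSON populations and
treatments, CSV encoding/KS/silencing tables, `report.md`) reproducibly
from a configuration and master seed.

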