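---
title: "Active-module detection in bipartite metabolic networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-module detection in bipartite metabolic networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(activemods)
```

## The model

A genome-scale metabolic reconstruction is represented as an undirected
bipartite graph: reaction nodes on one side, metabolite nodes on the other,
with an edge wherever a metabolite participates in a reaction. Reactions
carry gene associations; metabolites carry none. Differential-expression
results enter as one row per gene (`log2fc`, and a p- or q-value).

Each reaction is scored by the **mean log2 fold-change of its associated
genes**,

\[ s_r = \frac{1}{|G_r|} \sum_{g \in G_r} \mathrm{log_2FC}(g), \]

and reactions with no measured gene receive the **median** of all computed
reaction scores, so that they are neutral rather than attractive or
repulsive. For the down-regulated direction all reaction scores are negated
*after* imputation; because the median is an odd function of its input, this
makes the down analysis on data \(D\) exactly the up analysis on \(-D\)
(verified to exact set equality in the test suite).

Each metabolite receives a connectivity penalty

\[ w_m = -c \, d_m, \]

where \(d_m\) is its reaction degree. Highly connected currency metabolites
(water, ATP, ...) are thereby expensive to include, which prevents modules
from short-circuiting through hubs. A module's score is the plain sum of its
members' \(s_r\) and \(w_m\).

## The search objective

The annealer optimises a binary on/off state over all nodes. The objective
is the sum of the scores of the **top `top_k` highest-scoring connected
components** of the on-subgraph, each clamped at zero (`top_k` equals the
number of modules that will be reported, 20 per direction by default).

Two properties of this choice matter in practice:

* It is what the analysis actually reports — the best `top_k` modules — so
  the optimiser and the report cannot disagree.
* Clamping at zero means a negative component can never lower the objective,
  which keeps the state space smooth: the annealer can pass through
  unprofitable intermediate shapes without being pushed back.

A consequence worth knowing: when positive singletons are plentiful relative
to `top_k`, merging nodes through a (negatively weighted) metabolite only
pays off once the component slots become scarce. On a 5-node toy network
with scores \(+2, +1, -5\) and bridge weight \(-0.2\), the optimum under
`top_k = 20` is the two singletons (objective 3), while under `top_k = 1` it
is the bridged pair (objective 2.8). Both optima are frozen as oracle values
in the tests. At genome scale (hundreds of positive reactions competing for
20 slots) the merged modules win, which is the regime the method is designed
for.

Moves are single-node toggles accepted with probability
\(\min(1, e^{\Delta/T})\) under a geometric temperature schedule; the best
state ever visited is kept, over several restarts. The C++ implementation
maintains components incrementally — union-find records for insertions and a
round-robin multi-source BFS with early exit for deletions — so a
genome-scale run (963 reactions, 600 metabolites) anneals in a few seconds.
On networks of at most 20 nodes the annealer is validated against
`exhaustive_module_search()`, an independent subset-enumeration oracle.

## Choosing the weight constant

`score_network()` defaults to \(c = 0.1\,\mathrm{sd}(s) / \tilde d\) (ten
percent of the reaction-score standard deviation at the median metabolite
degree), and the chosen value is always written to the run log. The default
is deliberately gentle; on dense draft reconstructions it can let the top
module sprawl.

For the synthetic benchmark studies shipped in the tests we calibrate

\[ c = \mathrm{sd}(s_r), \]

one score standard deviation per unit of metabolite connectivity: a
metabolite is worth including only if each edge it brings contributes more
than one standard deviation of signal. In a sweep at genome scale, half this
value let modules sprawl mildly, 1.5 times it occasionally fragmented the
planted module, and the calibrated value recovered 20 of 20 planted modules
at Jaccard \(\ge 0.88\). `c` remains a configuration knob; any study should
report the value used (the pipeline log does so automatically).

## Synthetic ground truth: why planted modules are closed

`plant_modules()` plants a module of composition \((R, M)\) as the **closed
neighbourhood** of a connected set of \(M\) metabolites whose adjacent
reactions number exactly \(R\): planted metabolites touch no reaction
outside the module. This is a well-posedness requirement, not a convenience.
If a planted metabolite kept an external neighbour reaction, any such
neighbour whose noisy score happens to be positive would join a score-sum
module at zero marginal cost (its connecting metabolite is already paid
for), so *no* method that maximises summed scores could exclude it — the
planted label would be unrecoverable by construction rather than genuinely
hard. The module's reactions still touch non-member metabolites, so the
boundary remains contested in the realistic direction (the search must
decide not to expand through them).

## Empirical significance and its selection-bias limitation

Each reported module of composition \((R, M)\) is compared against `B`
random **connected node sets of the same composition**, grown by uniform
frontier expansion over the same network (an unconnected variant is
available behind a flag for comparison). The empirical p-value uses the
add-one estimator \(p = (r + 1)/(B + 1)\), where \(r\) counts null sets
scoring at least as high; with `B = 249` the smallest attainable value is
\(1/250 = 0.004\), and the report prints such entries as `<0.004` because
the p (and hence q) is then only an upper bound. Up- and down-module
families are corrected **jointly** (Benjamini–Hochberg by default, Storey's
method optionally).

Applied to *unselected* random modules these p-values are calibrated (the
test suite checks near-uniformity). Applied to search-selected modules they
are anti-conservative, because the reported modules are order statistics of
the very score the null measures: on a pure-noise network the best of
roughly \(N\) candidate compositions sits at \(p \approx k/N\) for rank
\(k\). Under BH at level \(\alpha\) over \(m\) reported modules, the top
module is declared significant whenever \(1/N \lesssim \alpha\,k/m\), i.e.
once the network offers \(N \ge m/(2\alpha)\) effective candidates — 400 at
the defaults — *every* null module can reach significance. We therefore ship
the calibration studies at a scale (150 reactions) where the empirical null
is honest for selected modules too, and recommend treating module q-values
at genome scale as a ranking device, not a literal error rate; the planted
ground-truth generator provides the stronger, assumption-free check.

## Pathway enrichment comparison

`fisher_enrich()` is the classical one-tailed Fisher's exact test, computed
as the hypergeometric survival function
`phyper(overlap - 1, size, N - size, n_de, lower.tail = FALSE)` and verified
against both a direct probability-mass sum and `fisher.test()` over an
exhaustive sweep of tables with \(N \le 200\). The DE gene list uses the
strict filter: fold-change **greater than** 2 and q **strictly below** 0.01.
Storey q-values (\(\hat\pi_0\) at \(\lambda = 0.5\)) at a 5% FDR are the
default for pathway calls.

## Numerical and reproducibility choices

* Every stochastic step takes an explicit integer seed; nothing is seeded
  from the clock. The pipeline derives stage seeds from the master seed by
  fixed offsets, and a given configuration reproduces every output byte.
* The run log records the network size, weight constant, annealing schedule
  (\(T_0\), \(\alpha\), budgets, restarts, seeds) and null size `B` — enough
  to reproduce a run from the log alone.
* Q-values are printed to two significant figures; scores to four decimals.

## Worked example

```{r example, eval = FALSE}
net <- generate_network(963, 600, mean_degree = 3, seed = 1)
truth <- plant_modules(net, list(c(8, 2)), "up", seed = 2)
genes <- plant_and_simulate(net, truth, seed = 3)
sc <- score_network(net, genes, direction = "up")
cfg <- run_config(net, genes, out_dir = "results",
                  c = sd(sc$reaction_score), seed = 1)
res <- run_pipeline(cfg)
res$module_table[1, ]
```

The top up-module recovers the planted reactions; `results/` holds
`modules.tsv`, the enrichment tables when a pathway map is supplied, and
`run_log.txt`.
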