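# dbnmit

Reverse engineering of gene regulatory networks from time-course expression
data with **globally optimal, high-order dynamic Bayesian networks** scored
by the **mutual information test (MIT)** metric.

Most DBN structure learners rely on hill climbing or stochastic global
optimization and return sub-optimal networks. For transition networks with
only inter-time-slice edges (time-delayed regulation — the biologically
plausible case), the parent set of every gene can be optimized
independently, and the MIT score admits a provably sufficient stopping rule
that makes exact global optimization polynomial. `dbnmit` implements:

* **The exhaustive-by-cardinality search ("plus" variant)** over all
  `n * d` lagged candidates: for child $X_i$ it minimizes

  $$ s(\mathbf{Pa}_i) = 2N_e\bigl(H_s(X_i) - I_s(X_i,\mathbf{Pa}_i)\bigr)
     + \sum_{j=1}^{|\mathbf{Pa}_i|}\chi_{\alpha,(k-1)^2 k^{j-1}}, $$

  where $I_s$ is the time-delayed mutual information on the lag-aware
  alignment and $N_e = \sum_i N_i - m d$ the effective observations.
  Cardinality level $p$ is skipped — and the search provably finished — as
  soon as the cumulative penalty $U(p)$ reaches the incumbent score, which
  bounds the enumeration at $p^\ast \sim \log_k N_e$.
* **The lag-restricted "star" variant** for large networks: each candidate
  regulator enters at its single MI-maximizing lag, shrinking the candidate
  set from `n * d` to `n` (first-order cost at any order `d`).
* Data handling: quantile discretization, cubic-spline upsampling,
  replicate averaging, multi-series alignment that never crosses series
  boundaries; TSV/SIF/GraphML I/O.
* Seeded synthetic benchmarks: a 35-gene, 4-level, 52-edge
  glucose-homeostasis cascade with order-1/2/3 interactions (13/23/16),
  random leveled cascades, static-then-shift and direct DBN simulators,
  shuffle negative controls.
* Evaluation: lag-aware / lag-agnostic sensitivity and precision against a
  lagged ground truth, degree distributions, and maximum-likelihood
  power-law exponent fitting.

## Worked example

```r
library(dbnmit)

gn  <- glucose_network()                       # 35 nodes, 52 lagged edges
sim <- simulate_static_then_shift(
  gn, sim_spec(q = 0.9, m = 3, n_obs = 50, k = 2, seed = 11))
dd  <- as_discrete_dataset(sim, 2)

net1 <- learn_network(dd, d = 1, variant = "plus")  # first-order, exact
net3 <- learn_network(dd, d = 3, variant = "star")  # order 3, lag-restricted
compare_networks(net1, gn)
#> <eval_report> [lag_agnostic] TP=13 FP=19 FN=39  Se=0.250 Pr=0.406  high-order TP=0
compare_networks(net3, gn)
#> <eval_report> [lag_agnostic] TP=36 FP=5 FN=16  Se=0.692 Pr=0.878  high-order TP=23
```

The first-order learner tops out at sensitivity 0.25 — exactly the 13/52
edges that are first-order — and recovers no delayed interaction. The
order-3 search nearly triples sensitivity (0.69 at precision 0.88) and
recovers 23 of the 39 order-2/3 interactions: time-delayed regulation is
invisible to first-order models and recoverable here.

Learned networks export with per-edge MI gains for ranking:

```r
head(as_edge_list(net3))
write_network(net3, "net.sif", format = "sif")
```

## Command line

A thin CLI over the same functions ships in `inst/cli/dbnmit.R`:

```sh
cli=$(Rscript -e 'cat(system.file("cli", "dbnmit.R", package = "dbnmit"))')
Rscript "$cli" simulate --template glucose --n-obs 50 --series 3 --seed 11 \
    --output-data expr.tsv --output-truth truth.tsv
Rscript "$cli" learn --input expr.tsv --series-lengths 50,50,50 --discrete \
    --k 2 --order 3 --variant star --output net.tsv
Rscript "$cli" evaluate --inferred net.tsv --truth truth.tsv
```

Subcommands: `learn`, `simulate`, `evaluate`, `discretize`, `upsample`,
`shuffle`, `degree-fit`. Exit codes: 0 success, 2 invalid input, 3 guard
exceeded.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main analysis from scratch —
glucose benchmark simulation, first-order and order-3 learning, evaluation
against the lagged truth, and power-law recovery — and writes a JSON
summary file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Method notes

See the vignette (`vignettes/mit-dbn-learning.Rmd`) for the model and its
assumptions, the stopping-rule argument, parameter guidance (`d`, `alpha`,
`k`, entropy vs `log k` bounds, self-loops), what the synthetic generators
do and do not emulate, and numerical choices (natural logarithms, plug-in
estimates, deterministic tie-breaking, guards).
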