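---
title: "Methods: propagation-based pathway annotation of lncRNA sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: propagation-based pathway annotation of lncRNA sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncprop)
```

## The model

`lncprop` annotates a *set* of lncRNAs with the pathways it influences by
treating influence as proximity in a coding/non-coding gene correlation
(CNC) network. The modelling assumptions are explicit:

* **Edges carry influence.** A lncRNA influences a protein-coding gene to
  the extent that the two are close in a network whose edges are consensus
  co-expression relationships and protein–protein interactions. Edge signs
  (positive/negative co-expression) are kept as metadata but do not enter
  the propagation: the walk runs on the unweighted, unsigned adjacency, so
  repression and activation contribute proximity equally.
* **Proximity is a steady-state visiting probability.** The random walk
  with restart, `p(t+1) = (1 - r) M p(t) + r p0`, with `M` the
  column-normalized adjacency and `p0` uniform over the mapped seeds, has a
  unique fixed point for any restart probability `r` in (0, 1]; power
  iteration contracts toward it at rate `1 - r` per step in L1.
* **Pathway influence is rank concentration.** If the seed set influences a
  pathway, the pathway's genes should cluster at the top of the list `L` of
  coding genes ranked by propagation score `t_j = sqrt(p_inf_j)`. That
  clustering is measured by a weighted Kolmogorov–Smirnov running sum and
  calibrated against random seed sets of the same size, so the null
  preserves the network topology and the pathway's own size and only
  randomizes *which* lncRNAs seed the walk.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `restart_probability` | 0.7 | Probability per step of returning to the seed distribution. Larger values localize the walk near the seeds; the ranking is known to be insensitive over roughly 0.1–0.9, and 0.7 keeps convergence fast (the L1 error shrinks by a factor 0.3 per iteration, about 20 iterations to 1e-10). |
| `tolerance` | 1e-10 | L1 convergence threshold, far below any score difference that could reorder `L` in practice. |
| `weight_exponent` | 1 | Exponent `p` on the propagation scores inside the running sum. `p = 0` recovers the classic unweighted KS statistic; `p = 1` weights pathway hits by how strongly the walk reaches them. |
| `min_size`, `max_size` | 15, 500 | Pathway size bounds, counted over genes present as coding nodes in the network; smaller sets give unstable running sums, larger ones are uninformatively broad. |
| `n_permutations` | 1000 | Null seed sets per run. p-values are discrete on a grid of 1/N; 1000 resolves an FDR threshold of 0.01. |
| `min_mean_fpkm`, `variance_keep_fraction` | 1, 0.75 | Expression filters applied per dataset before correlation: genes must exceed mean FPKM 1 and sit in the top 75% by FPKM variance. |
| `rank_fraction`, `alpha` | 0.001, 0.01 | A gene pair is co-expressed in a dataset when its absolute correlation is within each endpoint's top 0.1% (ties kept) *and* both endpoint-adjusted p-values are below 0.01. |
| `min_support` | 3 | Datasets that must agree (same pair, same sign) for a consensus edge. |

## Design choices where the design was open

Several details of the procedure admit more than one reasonable reading; the
package fixes them as follows.

* **Fisher-z standard error.** The z-statistic for a correlation from `N`
  samples is scaled by the textbook standard error `1/sqrt(N - 3)`, the
  standard companion of the `z = 0.5[ln(1+r) - ln(1-r)]` transform. Because
  each gene's z-scores are subsequently standardized to zero mean and unit
  variance, this scaling is a no-op within a dataset, but it keeps the
  intermediate columns interpretable.
* **Both endpoints, not either.** A pair receives two standardized
  z-values, one from each endpoint's distribution, and two Bonferroni
  families (the pairs involving that gene). The pair must pass the rank
  rule and the significance threshold from *both* endpoints; this is the
  conservative reading of a per-gene rule, and `endpoint_rule = "either"`
  is available for the permissive one.
* **Running-sum normalization.** `F_InP` divides the cumulative weighted
  hits by `N_R`, the total weight of pathway genes, so both running
  fractions terminate at exactly 1 and the ES is invariant to rescaling all
  scores — the GSEA convention for weighted statistics.
* **Signed maximum, not maximum deviation.** `ES(P)` is the plain maximum
  of the running sum: the test is one-sided toward top-of-list enrichment,
  and the permutation count `M` uses strict `ES_null > ES_obs`. Since the
  running sum ends at 0, the ES is never negative; a pathway whose genes
  sit at the bottom of `L` scores 0.
* **Peak ties and empty cores.** The peak index is the *smallest* position
  attaining the maximum, making core-gene sets deterministic. When the
  running sum never rises above zero the peak is reported as 0 and the core
  set is empty.
* **p-values.** Reported as `M/N` exactly; a `(M+1)/(N+1)` pseudocount
  variant (`pseudocount_pvalue = TRUE`) avoids literal zeros when that
  matters downstream. Benjamini–Hochberg adjustment is delegated to
  `stats::p.adjust`.
* **Permutation pool.** Null seeds are drawn uniformly without replacement
  from *all* lncRNA nodes of the network; `seed_pool` lets the user supply
  a restricted pool (e.g. expressed lncRNAs only). One permuted ranking is
  computed per permutation and scored against every pathway.
* **Isolated nodes and unmapped seeds.** Zero-degree nodes are removed
  before normalization rather than patched with teleportation columns, so
  `M` stays a plain column-normalized adjacency. Seeds absent from the
  network (or not lncRNAs) are dropped with a warning and counted in the
  run manifest; seeds in small components are allowed, and probability mass
  then remains inside their components. Pathways whose genes all carry zero
  score are an error for the observed run and an excluded `NA` inside the
  permutation null.
* **Degree power law.** The scale-free QC fits ordinary least squares on
  `(log k, log P(k))` over degrees with nonzero frequency and reports the
  negative slope and R²; this matches the descriptive use of the fit (a
  goodness-of-fit check), not a maximum-likelihood exponent estimate.
* **Consensus sign conflicts.** A pair flagged positive in some datasets
  and negative in others has each direction counted separately; in the rare
  case both directions reach `min_support`, both survive consensus and the
  network builder keeps the first and warns.

## The synthetic-data generator

`generate_cnc()` emulates the structural features the method relies on: a
scale-free topology (preferential attachment, 2 edges per new node, giving
`1 + 2(n-2)` edges on `n` nodes), a 10% lncRNA / 90% coding biotype mix at
1,000 nodes, 5 seed lncRNAs, and a 30-gene pathway planted within 2 hops of
the seeds among 20 size-matched random decoys — the "ground truth" knob
standing in for genes that are genuinely close to the source nodes.
`generate_fpkm()` emulates the co-expression inputs: 3 datasets of 20
samples, log-normal background expression with gene-specific baselines
(`meanlog ~ U(-1, 4)`, so a realistic fraction fails the mean-FPKM filter),
and 10 planted pairs at Pearson correlation 0.98 recurring in every
dataset. Planted responses are generated on the linear FPKM scale because
that is the scale the correlation filter operates on; a strongly negative
correlation planted on the log scale would attenuate to a weak linear one
under exponentiation, which is also why negative consensus edges are rarer
than positive ones in real FPKM data.

What the generator does *not* emulate: RNA-Seq count noise and
mean–variance coupling, batch structure across datasets, hub-biased
biotype placement, and correlated (overlapping) pathways. Passing tests
therefore demonstrate that the algorithms are implemented correctly and
behave as designed under clean conditions — not that the biological signal
in any particular real dataset is recoverable.

## Validation problem sizes

The test suite and `scripts/acceptance.R` validate at sizes chosen to make
every check exact or tightly repeatable: random-walk correctness against a
dense linear solve on 100 random connected graphs of up to 50 nodes (where
`solve()` is exact to machine precision); the enrichment score against a
brute-force unweighted KS oracle on 1,000 random rankings of up to 200
genes; null calibration with 200 permutations and 100 decoy pathways on a
1,000-node network; planted-signal power over 100 replicate 1,000-node
networks; and co-expression recovery over 3 datasets of ~1,020 genes.
Because the 100 decoy p-values in the calibration check share one observed
ranking and one set of permutations, they are exchangeable but not
independent, and the Kolmogorov–Smirnov uniformity check is approximate.

## Known limitations

* Results are conditional on the input network; co-expression consensus
  from few datasets favors strongly, consistently co-expressed pairs, and
  PPI coverage biases coding-gene connectivity.
* All seed lncRNAs are weighted equally in `p0`; there is no notion of the
  strength of a lncRNA's association with the condition of interest.
* The permutation null randomizes seeds only. It conditions on the
  pathway's position structure in the network, not on co-membership
  between pathways, so FDR across strongly overlapping pathways is
  approximate.
* Empirical p-values are bounded below by `1/N`; pathway rankings below
  that resolution are distinguished by ES only.
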