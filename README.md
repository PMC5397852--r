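# lncprop

Pathway annotation for sets of long non-coding RNAs (lncRNAs) by global
network propagation.

## The problem

Most lncRNAs have no annotated function, and methods that annotate them one
at a time miss effects that only emerge from a *set* of lncRNAs acting
together — for example, the lncRNAs differentially expressed between tumor
and normal samples. `lncprop` asks which biological pathways are influenced
by the combinatorial effect of such a set. It is aimed at computational
biologists who have (i) a mixed coding/non-coding gene network — consensus
co-expression edges merged with protein–protein interactions (a "CNC"
network) — or the multi-dataset FPKM matrices to build one, (ii) a seed list
of lncRNAs of interest, and (iii) pathway gene sets in GMT format.

## The method

1. **Propagation.** The seed lncRNAs are mapped to the network as source
   nodes and a random walk with restart is iterated to its steady state,

   p⁽ᵗ⁺¹⁾ = (1 − r) M p⁽ᵗ⁾ + r p⁽⁰⁾,

   where *M* is the column-normalized adjacency matrix, *p⁽⁰⁾* spreads unit
   mass equally over the seeds, and the restart probability is r = 0.7.
   Iteration stops when the L1 change falls below 10⁻¹⁰. Each protein-coding
   gene *j* receives a propagation score t_j = √(steady-state probability),
   and all coding genes are ranked into a list L by descending t_j.

2. **Pathway scoring.** Each pathway P (size-filtered to 15–500 genes
   present in the network) is scored with a propagation-score-weighted
   Kolmogorov–Smirnov running sum walked down L:

   F_InP(i) = Σ_{g_j ∈ P, j ≤ i} t_jᵖ / N_R,  N_R = Σ_{g_j ∈ P} t_jᵖ,
   F_NotP(i) = #{g_j ∉ P, j ≤ i} / N_NotP,

   with weight exponent p = 1. ES(P) = maxᵢ [F_InP(i) − F_NotP(i)]; it
   approaches 1 when pathway genes concentrate at the top of L. The pathway
   genes ranked at or before the peak are its **core genes**.

3. **Significance.** N = 1000 random seed sets of the same size are drawn
   from the network's lncRNA nodes; each is propagated and scored, giving a
   null ES distribution per pathway. The empirical p-value is M/N with M the
   number of null scores exceeding the observed ES, followed by
   Benjamini–Hochberg adjustment.

The package also ships the co-expression pipeline used to construct CNC
networks from FPKM matrices (mean/variance gene filters, Fisher z transform
with per-gene standardization, per-gene Bonferroni correction, top/bottom
0.1% rank rule, ≥3-dataset same-sign consensus) and a synthetic-data
generator with planted ground truth used throughout the test suite.

## Worked example

```r
library(lncprop)

sim <- generate_cnc(synthetic_spec(rng_seed = 7))   # 1,000-node network
res <- lnc_pathways(sim$network, sim$seeds,
                    c(list(sim$planted_pathway), sim$decoys),
                    n_permutations = 1000, rng_seed = 7)
head(res[, c("pathway_id", "size", "es", "p_value", "fdr", "peak_index")], 5)
#>   pathway_id size        es p_value   fdr peak_index
#> 1    PLANTED   30 0.9146413   0.001 0.021         95
#> 2   DECOY020   30 0.7353659   0.070 0.735         86
#> 3   DECOY015   30 0.7265273   0.114 0.798         33
#> 4   DECOY003   30 0.6988703   0.318 0.910        149
#> 5   DECOY014   30 0.6760252   0.330 0.910         94
```

The synthetic network contains a 30-gene pathway planted within two hops of
the five seed lncRNAs plus twenty size-matched random decoys. The planted
pathway tops the ranking with ES = 0.91 — its genes cluster tightly at the
head of the propagation-ranked list, with the 95 top-ranked genes containing
all the core members — and it is the only pathway significant after FDR
adjustment (0.021; the decoys' p-values scatter over (0, 1]). The
propagation itself converged in 18 iterations over the 1,000-node network:

```r
attr(res, "propagation")
#> <rwr_result> 1000 nodes, 5 seeds ( 0 dropped ), 18 iterations, L1 residual 3.289492e-11
#>   ranked list: 900 coding genes, top: PC00155, PC00098, PC00183 ...
```

A command-line interface wraps the same functions
(`exec/lncprop run|build-network|simulate`), writing a results TSV plus a
JSON manifest that suffices to replay the run.

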