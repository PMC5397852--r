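#' Pathway annotation of a lncRNA set by network propagation
#'
#' End-to-end analysis: restricts the network to its connected (non-isolated)
#' nodes, runs the random walk with restart from the seed lncRNAs, ranks all
#' protein-coding genes by propagation score, size-filters the pathways,
#' computes each pathway's weighted enrichment score, core genes and
#' seed-permutation p-value, and applies Benjamini-Hochberg correction.
#'
#' @param net A [cnc_network()].
#' @param seeds Character vector of seed lncRNA identifiers.
#' @param pathways List of [pathway_gene_set()] objects.
#' @param restart_probability Restart probability `r`. Default 0.7.
#' @param tolerance L1 convergence threshold. Default 1e-10.
#' @param max_iterations Iteration cap. Default 10000.
#' @param n_permutations Seed permutations `N` (0 disables the test and
#'   leaves p-values `NA`). Default 1000.
#' @param weight_exponent Score weight exponent `p`. Default 1.
#' @param min_size,max_size Pathway size bounds (network-present genes).
#'   Defaults 15 and 500.
#' @param rng_seed Integer RNG seed for the permutation null. Default 1.
#' @param pseudocount_pvalue Use `(M+1)/(N+1)` p-values. Default `FALSE`.
#' @return data.frame of class `lnc_pathways_result` with columns
#'   `pathway_id`, `name`, `size`, `es`, `p_value`, `fdr`, `peak_index`,
#'   `core_genes` (semicolon-separated, rank order), ordered by descending
#'   `es` with ties broken by `pathway_id`. The propagation result, the
#'   dropped-seed count and the run settings are attached as attributes
#'   `"propagation"`, `"n_dropped_seeds"` and `"settings"`.
#' @examples
#' sim <- generate_cnc(synthetic_spec(rng_seed = 7))
#' res <- lnc_pathways(sim$network, sim$seeds,
#'                     c(list(sim$planted_pathway), sim$decoys),
#'                     n_permutations = 50, rng_seed = 7)
#' head(res[, c("pathway_id", "size", "es", "p_value", "fdr")])
#' @export
lnc_pathways <- function(net, seeds, pathways,
                         restart_probability = 0.7,
                         tolerance = 1e-10,
                         max_iterations = 10000L,
                         n_permutations = 1000L,
                         weight_exponent = 1,
                         min_size = 15L, max_size = 500L,
                         rng_seed = 1L,
                         pseudocount_pvalue = FALSE) {
  cfg <- propagation_config(restart_probability, tolerance, max_iterations)
  net <- restrict_to_components(net)$network
  prop <- rank_coding_genes(rwr(net, seeds, cfg), net)
  paths <- filter_pathways(pathways, net, min_size, max_size)

  empty <- data.frame(pathway_id = character(), name = character(),
                      size = integer(), es = numeric(), p_value = numeric(),
                      fdr = numeric(), peak_index = integer(),
                      core_genes = character(), stringsAsFactors = FALSE)
  if (length(paths) == 0L) {
    out <- empty
  } else {
    rows <- lapply(paths, function(p) {
      sc <- enrichment_score(prop, p, weight_exponent)
      core <- core_genes(prop, p, sc$peak_index)
      data.frame(pathway_id = p$pathway_id, name = p$name, size = p$size,
                 es = sc$es, p_value = NA_real_, fdr = NA_real_,
                 peak_index = sc$peak_index,
                 core_genes = paste(core, collapse = ";"),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (n_permutations > 0L) {
      perm <- permutation_test(net, length(prop$seed_ids), paths, cfg,
                               n_permutations, rng_seed,
                               observed_es = stats::setNames(out$es,
                                                             out$pathway_id),
                               weight_exponent = weight_exponent,
                               pseudocount = pseudocount_pvalue)
      out$p_value <- perm$p_value[match(out$pathway_id, perm$pathway_id)]
      out$fdr <- bh_fdr(out$p_value)
    }
    out <- out[order(-out$es, out$pathway_id), ]
    rownames(out) <- NULL
  }
  attr(out, "propagation") <- prop
  attr(out, "n_dropped_seeds") <- prop$n_dropped
  attr(out, "settings") <- list(restart_probability = restart_probability,
                                tolerance = tolerance,
                                max_iterations = max_iterations,
                                n_permutations = n_permutations,
                                weight_exponent = weight_exponent,
                                min_size = min_size, max_size = max_size,
                                rng_seed = rng_seed,
                                pseudocount_pvalue = pseudocount_pvalue)
  class(out) <- c("lnc_pathways_result", class(out))
  out
}

#' Build a CNC network from expression datasets and a PPI list
#'
#' Convenience pipeline over the co-expression module: gene-filters each
#' dataset, extracts its co-expressed pairs, forms cross-dataset consensus
#' edges and merges them with the protein-protein interactions.
#'
#' @param datasets List of [expression_dataset()] objects.
#' @param ppi data.frame of PPI pairs (`gene_a`, `gene_b`); may be empty.
#' @param min_mean_fpkm,variance_keep_fraction Gene-filter settings, see
#'   [filter_genes()].
#' @param rank_fraction,alpha,endpoint_rule Co-expression settings, see
#'   [dataset_coexpression()].
#' @param min_support Consensus support threshold. Default 3.
#' @return A [cnc_network()]; the consensus edge table is attached as
#'   attribute `"consensus"`.
#' @export
build_cnc_from_expression <- function(datasets, ppi = NULL,
                                      min_mean_fpkm = 1,
                                      variance_keep_fraction = 0.75,
                                      rank_fraction = 0.001, alpha = 0.01,
                                      endpoint_rule = "both",
                                      min_support = 3L) {
  per_ds <- lapply(datasets, function(ds)
    dataset_coexpression(filter_genes(ds, min_mean_fpkm,
                                      variance_keep_fraction),
                         rank_fraction, alpha, endpoint_rule))
  cons <- consensus_edges(per_ds, min_support)
  biotypes <- unlist(lapply(datasets, function(ds) ds$biotype))
  biotypes <- biotypes[!duplicated(names(biotypes))]
  net <- build_network(cons, ppi, biotypes)
  attr(net, "consensus") <- cons
  net
}
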