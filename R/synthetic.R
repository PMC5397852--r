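#' Specification for the synthetic fixture generator
#'
#' Describes a scale-free mixed-biotype network with a pathway planted near
#' the seed lncRNAs, plus multi-dataset FPKM matrices with planted
#' correlated gene pairs. The defaults mirror the study conditions the
#' pipeline is validated under: a 1,000-node preferential-attachment network
#' (10% lncRNA), 5 seeds, a 30-gene pathway within 2 hops of the seeds,
#' 20 size-matched decoys, and 3 expression datasets of 20 samples with
#' pairs planted at correlation 0.98.
#'
#' @param n_coding,n_lnc Node counts by biotype.
#' @param attachment Edges added per new node by preferential attachment.
#' @param n_seeds Number of seed lncRNAs.
#' @param planted_pathway_size Genes in the planted pathway.
#' @param planted_proximity Maximum hop distance from any seed to a planted
#'   pathway gene.
#' @param n_decoy_pathways Number of size-matched random decoy pathways.
#' @param rng_seed Integer seed; generators are pure functions of the spec.
#' @param fpkm List of expression-generator settings: `n_genes`,
#'   `n_datasets`, `n_samples`, `n_planted_pairs`, `planted_correlation`
#'   (in (0,1)), `noise_sd` (log-scale within-gene sd), `negative_fraction`
#'   (fraction of planted pairs with negative correlation).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_coding = 900L, n_lnc = 100L, attachment = 2L,
                           n_seeds = 5L, planted_pathway_size = 30L,
                           planted_proximity = 2L, n_decoy_pathways = 20L,
                           rng_seed = 1L,
                           fpkm = list()) {
  fp <- utils::modifyList(list(n_genes = 1000L, n_datasets = 3L,
                               n_samples = 20L, n_planted_pairs = 10L,
                               planted_correlation = 0.98,
                               noise_sd = 0.5,
                               negative_fraction = 0),
                          fpkm)
  stopifnot(n_coding > 0, n_lnc > 0, attachment > 0, n_seeds > 0,
            planted_pathway_size > 0, planted_proximity > 0,
            n_decoy_pathways >= 0,
            fp$planted_correlation > 0, fp$planted_correlation < 1,
            fp$n_samples >= 6L)
  structure(list(n_coding = as.integer(n_coding),
                 n_lnc = as.integer(n_lnc),
                 attachment = as.integer(attachment),
                 n_seeds = as.integer(n_seeds),
                 planted_pathway_size = as.integer(planted_pathway_size),
                 planted_proximity = as.integer(planted_proximity),
                 n_decoy_pathways = as.integer(n_decoy_pathways),
                 rng_seed = as.integer(rng_seed),
                 fpkm = fp),
            class = "synthetic_spec")
}

# Number of edges the preferential-attachment rule produces for n nodes and
# m edges per new node: node 2 can attach to only 1 earlier node.
pa_edge_count <- function(n, m) {
  sum(pmin(m, seq_len(n - 1L)))
}

#' Generate a synthetic CNC network with planted ground truth
#'
#' Builds an undirected preferential-attachment (scale-free) graph, assigns
#' biotypes at random in the requested proportions, picks seed lncRNAs, and
#' plants a pathway by sampling coding genes within `planted_proximity` hops
#' of the seeds. Decoy pathways are size-matched uniform random coding-gene
#' sets. Fully reproducible from `spec$rng_seed`.
#'
#' Edge provenance is assigned for realism only: coding-coding edges are
#' labelled `ppi` with probability 1/2, all other edges `coexpression`
#' (co-expression edges get a sign, positive with probability 0.8).
#'
#' @param spec A [synthetic_spec()].
#' @return List with `network` ([cnc_network()]), `seeds`,
#'   `planted_pathway` ([pathway_gene_set()]), `decoys` (list of
#'   pathway_gene_set) and `spec`.
#' @export
generate_cnc <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$rng_seed)
  n <- spec$n_coding + spec$n_lnc
  g <- igraph::sample_pa(n, power = 1, m = spec$attachment,
                         directed = FALSE)

  lnc_idx <- sample.int(n, spec$n_lnc)
  biotype <- rep("coding", n)
  biotype[lnc_idx] <- "lncRNA"
  ids <- character(n)
  ids[biotype == "coding"] <- sprintf("PC%05d", seq_len(spec$n_coding))
  ids[biotype == "lncRNA"] <- sprintf("LNC%04d", seq_len(spec$n_lnc))
  igraph::V(g)$name <- ids

  el <- igraph::as_edgelist(g)
  pc <- canonical_pairs(el[, 1L], el[, 2L])
  both_coding <- biotype[match(pc$gene_a, ids)] == "coding" &
    biotype[match(pc$gene_b, ids)] == "coding"
  provenance <- ifelse(both_coding & stats::runif(nrow(el)) < 0.5,
                       "ppi", "coexpression")
  sgn <- ifelse(provenance == "coexpression",
                ifelse(stats::runif(nrow(el)) < 0.8, 1L, -1L),
                NA_integer_)
  net <- cnc_network(
    data.frame(gene_id = ids, biotype = biotype, stringsAsFactors = FALSE),
    data.frame(gene_a = pc$gene_a, gene_b = pc$gene_b,
               provenance = provenance, sign = sgn,
               stringsAsFactors = FALSE))

  seeds <- sample(ids[biotype == "lncRNA"], spec$n_seeds)
  near <- unique(unlist(lapply(
    igraph::ego(g, order = spec$planted_proximity,
                nodes = seeds), names)))
  near_coding <- setdiff(near[biotype[match(near, ids)] == "coding"], seeds)
  if (length(near_coding) < spec$planted_pathway_size)
    stop("only ", length(near_coding), " coding genes within ",
         spec$planted_proximity, " hops of the seeds; increase ",
         "planted_proximity or reduce planted_pathway_size")
  planted <- pathway_gene_set(
    "PLANTED", "pathway planted near the seed lncRNAs",
    sort(sample(near_coding, spec$planted_pathway_size)))

  coding_ids <- ids[biotype == "coding"]
  decoys <- lapply(seq_len(spec$n_decoy_pathways), function(k)
    pathway_gene_set(sprintf("DECOY%03d", k),
                     "size-matched random coding-gene set",
                     sort(sample(coding_ids, spec$planted_pathway_size))))

  list(network = net, seeds = seeds, planted_pathway = planted,
       decoys = decoys, spec = spec)
}

#' Generate multi-dataset FPKM matrices with planted correlated pairs
#'
#' Produces `n_datasets` expression datasets sharing the same genes.
#' Background genes are log-normal with a gene-specific baseline
#' (`meanlog ~ U(-1, 4)`, shared across datasets) and within-gene log-scale
#' noise `noise_sd`. Each planted pair couples a log-normal driver gene
#' (`meanlog` 2, log-sd 1) with a linear response at the requested Pearson
#' correlation on the FPKM scale (shifted to stay non-negative), with the
#' sign set by `negative_fraction`; the same pairs recur in every dataset.
#' Planted pairs link one lncRNA to one coding gene; background genes are
#' 10% lncRNA.
#'
#' @param spec A [synthetic_spec()]; the `fpkm` element controls sizes.
#' @return List with `datasets` (list of [expression_dataset()]) and
#'   `manifest` (data.frame `gene_a`, `gene_b`, `sign` of planted pairs).
#' @export
generate_fpkm <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  fp <- spec$fpkm
  set.seed(spec$rng_seed + 104729L)  # distinct stream from generate_cnc
  n_bg <- fp$n_genes
  n_pp <- fp$n_planted_pairs
  bg_ids <- sprintf("BG%05d", seq_len(n_bg))
  pair_a <- sprintf("PLA%03d", seq_len(n_pp))  # lncRNA side
  pair_b <- sprintf("PLB%03d", seq_len(n_pp))  # coding side
  ids <- c(bg_ids, rbind(pair_a, pair_b))
  biotype <- c(ifelse(stats::runif(n_bg) < 0.1, "lncRNA", "coding"),
               rep(c("lncRNA", "coding"), n_pp))
  names(biotype) <- ids

  signs <- rep(1L, n_pp)
  if (n_pp > 0 && fp$negative_fraction > 0)
    signs[seq_len(floor(fp$negative_fraction * n_pp))] <- -1L
  manifest <- if (n_pp > 0)
    data.frame(gene_a = pair_a, gene_b = pair_b, sign = signs,
               stringsAsFactors = FALSE)
  else data.frame(gene_a = character(), gene_b = character(),
                  sign = integer(), stringsAsFactors = FALSE)

  meanlog_bg <- stats::runif(n_bg, -1, 4)  # shared baseline across datasets
  ns <- fp$n_samples
  datasets <- lapply(seq_len(fp$n_datasets), function(d) {
    x <- matrix(0, nrow = length(ids), ncol = ns,
                dimnames = list(ids, sprintf("S%02d", seq_len(ns))))
    x[bg_ids, ] <- exp(meanlog_bg +
                         fp$noise_sd * stats::rnorm(n_bg * ns))
    for (k in seq_len(n_pp)) {
      rho <- fp$planted_correlation
      a_vals <- exp(2 + stats::rnorm(ns))
      b_vals <- signs[k] * a_vals +
        stats::sd(a_vals) * sqrt(1 / rho^2 - 1) * stats::rnorm(ns)
      # shift to non-negative FPKM; a constant offset leaves r unchanged
      x[pair_a[k], ] <- a_vals
      x[pair_b[k], ] <- b_vals - min(b_vals) + 1
    }
    expression_dataset(sprintf("synthetic_ds%02d", d), x, biotype)
  })
  list(datasets = datasets, manifest = manifest)
}
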