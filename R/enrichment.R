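#' Size-filter pathways against the network
#'
#' Keeps pathways whose number of member genes present as coding nodes in
#' the network lies in `[min_size, max_size]`. Overly narrow or broad
#' functional categories are removed before scoring; the size used
#' everywhere downstream counts network-present genes only.
#'
#' @param pathways List of [pathway_gene_set()] objects.
#' @param net A [cnc_network()].
#' @param min_size,max_size Inclusive size bounds. Defaults 15 and 500.
#' @return The retained pathways, each with a `size` element filled in.
#' @export
filter_pathways <- function(pathways, net, min_size = 15L, max_size = 500L) {
  stopifnot(inherits(net, "cnc_network"))
  coding <- net$nodes$gene_id[net$nodes$biotype == "coding"]
  kept <- list()
  for (p in pathways) {
    sz <- length(intersect(p$genes, coding))
    if (sz >= min_size && sz <= max_size) {
      p$size <- sz
      kept[[length(kept) + 1L]] <- p
    }
  }
  kept
}

# Scores must be a named numeric vector in descending rank order
as_ranked_scores <- function(ranked) {
  if (inherits(ranked, "rwr_result")) {
    if (is.null(ranked$propagation_scores))
      stop("run rank_coding_genes() first")
    return(ranked$propagation_scores)
  }
  stopifnot(is.numeric(ranked), !is.null(names(ranked)))
  ranked
}

#' Propagation-score-weighted enrichment score
#'
#' Walks down the ranked coding-gene list `L`: the running sum increases by
#' a gene's weighted propagation score (normalized so the in-pathway
#' fraction ends at 1) at pathway genes and decreases by `1/N_NotP` at
#' non-pathway genes. The enrichment score `ES(P)` is the maximum of the
#' running sum `F_InP - F_NotP`; it approaches 1 when pathway genes
#' concentrate at the top of `L` and is near 0 for randomly scattered genes.
#' With `weight_exponent = 0` the statistic reduces to the classic
#' unweighted Kolmogorov-Smirnov enrichment score.
#'
#' @param ranked An `rwr_result` processed by [rank_coding_genes()], or a
#'   named numeric vector of scores in descending rank order.
#' @param pathway A [pathway_gene_set()].
#' @param weight_exponent Exponent `p` applied to the propagation scores of
#'   pathway genes. Default 1.
#' @return List with `es`, `peak_index` (smallest position attaining the
#'   maximum; 0 when the running sum never rises above zero) and
#'   `running_sum`.
#' @export
enrichment_score <- function(ranked, pathway, weight_exponent = 1) {
  scores <- as_ranked_scores(ranked)
  in_p <- names(scores) %in% pathway$genes
  n <- length(scores)
  n_hit <- sum(in_p)
  if (n_hit == 0L)
    stop("pathway '", pathway$pathway_id, "' has no genes in the ranked list")
  if (n_hit == n)
    stop("pathway covers the entire ranked list")
  w <- scores ^ weight_exponent
  n_r <- sum(w[in_p])
  if (n_r == 0)
    stop("pathway unreachable from seeds (all propagation scores zero): ",
         pathway$pathway_id)
  f_in <- cumsum(ifelse(in_p, w, 0)) / n_r
  f_not <- cumsum(!in_p) / (n - n_hit)
  run <- f_in - f_not
  es <- max(run)
  peak <- if (es > 0) which(run == es)[1L] else 0L
  list(es = es, peak_index = as.integer(peak), running_sum = run)
}

# ES from hit positions only: equivalent to enrichment_score() but O(|P|)
# given the rank position of each pathway gene. The running sum attains its
# maximum at a pathway-gene position, so only those need inspection.
es_from_positions <- function(pos, w_at_pos, n, n_r, n_not) {
  o <- order(pos)
  pos <- pos[o]
  f_in <- cumsum(w_at_pos[o]) / n_r
  f_not <- (pos - seq_along(pos)) / n_not
  es <- max(f_in - f_not)
  if (es > 0) es else {
    # running sum never positive; its supremum over all n positions is 0
    # (attained at the end of the list where both fractions reach 1)
    0
  }
}

#' Core genes of a pathway
#'
#' The pathway genes appearing in the ranked list at or before the position
#' where the enrichment score is attained -- the members that drive the
#' signal. A `peak_index` of 0 (running sum never positive) yields an empty
#' core set.
#'
#' @param ranked As in [enrichment_score()].
#' @param pathway A [pathway_gene_set()].
#' @param peak_index Peak position from [enrichment_score()].
#' @return Character vector of core genes in rank order.
#' @export
core_genes <- function(ranked, pathway, peak_index) {
  scores <- as_ranked_scores(ranked)
  if (peak_index <= 0L) return(character(0))
  top <- names(scores)[seq_len(peak_index)]
  top[top %in% pathway$genes]
}

#' Seed-permutation significance test
#'
#' Draws `n_permutations` random seed sets of `seed_count` lncRNA nodes
#' (uniformly, without replacement, from all lncRNA nodes of the network by
#' default), reruns the random walk and coding-gene ranking once per
#' permutation, and scores every pathway against the permuted ranking. The
#' empirical p-value of a pathway is `M/N`, where `M` counts null enrichment
#' scores strictly greater than the observed one. Permutations in which a
#' pathway receives zero total propagation score are recorded as `NA` and
#' excluded from that pathway's `N`.
#'
#' @param net A [cnc_network()] without zero-degree nodes.
#' @param seed_count Number of lncRNA seeds per permutation (match the
#'   number of mapped observed seeds).
#' @param pathways List of size-filtered [pathway_gene_set()] objects.
#' @param cfg A [propagation_config()].
#' @param n_permutations Number of permutations `N`. Default 1000.
#' @param rng_seed Integer seed for the permutation RNG (recorded in the
#'   output for reproducibility).
#' @param observed_es Named numeric vector of observed enrichment scores,
#'   names matching the pathway ids.
#' @param weight_exponent Exponent `p`. Default 1.
#' @param pseudocount If `TRUE`, report `(M + 1)/(N + 1)` instead of `M/N`
#'   to avoid literal zero p-values. Default `FALSE`.
#' @param seed_pool Optional character vector restricting the lncRNA pool
#'   the null seeds are drawn from.
#' @return data.frame with columns `pathway_id`, `p_value`, `n_valid`,
#'   `null_mean`, `null_sd`; the full null ES matrix (permutations x
#'   pathways) is attached as attribute `"es_null"` and the RNG seed as
#'   `"rng_seed"`.
#' @export
permutation_test <- function(net, seed_count, pathways,
                             cfg = propagation_config(),
                             n_permutations = 1000L, rng_seed = 1L,
                             observed_es = NULL, weight_exponent = 1,
                             pseudocount = FALSE, seed_pool = NULL) {
  stopifnot(inherits(net, "cnc_network"), seed_count >= 1L)
  pool <- if (is.null(seed_pool))
    net$nodes$gene_id[net$nodes$biotype == "lncRNA"]
  else as.character(seed_pool)
  if (length(pool) < seed_count)
    stop("network has fewer lncRNA nodes (", length(pool),
         ") than seed_count (", seed_count, ")")
  ids <- vapply(pathways, function(p) p$pathway_id, "")

  null_es <- matrix(NA_real_, nrow = n_permutations, ncol = length(pathways),
                    dimnames = list(NULL, ids))
  set.seed(rng_seed)
  if (n_permutations > 0L) {
    # precompute once; the walk itself depends only on the seed draw
    universe <- NULL
    path_idx <- NULL
    any_unreachable <- FALSE
    for (b in seq_len(n_permutations)) {
      perm_seeds <- sample(pool, seed_count)
      res <- rank_coding_genes(rwr(net, perm_seeds, cfg), net)
      scores <- res$propagation_scores
      if (is.null(universe)) {
        universe <- sort(names(scores))
        path_idx <- lapply(pathways, function(p)
          which(universe %in% p$genes))
      }
      pos_of <- match(universe, names(scores))  # rank of each universe gene
      n <- length(scores)
      w <- scores ^ weight_exponent
      for (k in seq_along(pathways)) {
        pos <- pos_of[path_idx[[k]]]
        if (length(pos) == 0L) next
        n_r <- sum(w[pos])
        if (n_r == 0) { any_unreachable <- TRUE; next }
        null_es[b, k] <- es_from_positions(pos, w[pos], n, n_r,
                                           n - length(pos))
      }
    }
    if (any_unreachable)
      warning("some permutations left pathway(s) unreachable; ",
              "recorded as NA")
  }

  p_value <- rep(NA_real_, length(pathways))
  n_valid <- colSums(!is.na(null_es))
  if (!is.null(observed_es) && n_permutations > 0L) {
    for (k in seq_along(pathways)) {
      obs <- observed_es[[ids[k]]]
      nulls <- null_es[!is.na(null_es[, k]), k]
      if (length(nulls) == 0L) next
      m <- sum(nulls > obs)
      p_value[k] <- if (pseudocount) (m + 1) / (length(nulls) + 1)
                    else m / length(nulls)
    }
  }
  out <- data.frame(pathway_id = ids,
                    p_value = p_value,
                    n_valid = as.integer(n_valid),
                    null_mean = colMeans(null_es, na.rm = TRUE),
                    null_sd = apply(null_es, 2L, stats::sd, na.rm = TRUE),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "es_null") <- null_es
  attr(out, "rng_seed") <- rng_seed
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false discovery rate adjustment; input order preserved.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted values.
#' @export
bh_fdr <- function(p_values) {
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Flag differentially expressed core genes
#'
#' Validation helper: a core gene is flagged when the absolute log2 fold
#' change of its mean FPKM between two conditions strictly exceeds the
#' threshold (default 1, i.e. FC > 2 or FC < 0.5). A zero mean in either
#' condition is handled by adding a small pseudocount to both means, noted
#' in the output. Genes missing from either condition are marked
#' `not_evaluable` and excluded from the summary fraction.
#'
#' @param core Character vector of core genes (rank order).
#' @param expr_case,expr_control Named numeric vectors of per-gene FPKM
#'   means, or genes x samples matrices (row means are taken).
#' @param log2fc_threshold Strict |log2 FC| threshold. Default 1.
#' @param zero_pseudocount Pseudocount used when a mean is zero.
#'   Default 0.01.
#' @return data.frame with columns `gene`, `log2fc`, `flagged`,
#'   `pseudocount_used`, `status`; the fraction of evaluable core genes
#'   flagged is attached as attribute `"fraction_flagged"`.
#' @export
flag_differential_core_genes <- function(core, expr_case, expr_control,
                                         log2fc_threshold = 1,
                                         zero_pseudocount = 0.01) {
  to_means <- function(x) if (is.matrix(x)) rowMeans(x) else x
  case <- to_means(expr_case)
  ctrl <- to_means(expr_control)
  n <- length(core)
  out <- data.frame(gene = core,
                    log2fc = rep(NA_real_, n),
                    flagged = rep(NA, n),
                    pseudocount_used = rep(FALSE, n),
                    status = rep("ok", n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    g <- core[i]
    if (!(g %in% names(case)) || !(g %in% names(ctrl))) {
      out$status[i] <- "not_evaluable"
      next
    }
    a <- case[[g]]; b <- ctrl[[g]]
    if (a == 0 || b == 0) {
      a <- a + zero_pseudocount
      b <- b + zero_pseudocount
      out$pseudocount_used[i] <- TRUE
    }
    out$log2fc[i] <- log2(a / b)
    out$flagged[i] <- abs(out$log2fc[i]) > log2fc_threshold
  }
  ev <- out$status == "ok"
  attr(out, "fraction_flagged") <-
    if (any(ev)) mean(out$flagged[ev]) else NA_real_
  out
}

#' Plot the enrichment running sum
#'
#' @param running_sum Numeric running-sum vector from [enrichment_score()].
#' @param main Plot title.
#' @return Invisibly, the peak position.
#' @export
plot_running_sum <- function(running_sum, main = "Running enrichment score") {
  graphics::plot(seq_along(running_sum), running_sum, type = "l",
                 xlab = "Rank in L", ylab = "F_InP - F_NotP", main = main)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  peak <- which.max(running_sum)
  graphics::abline(v = peak, lty = 3, col = "red")
  invisible(peak)
}
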