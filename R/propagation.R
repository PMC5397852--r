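#' Column-normalized transition matrix
#'
#' Divides each column of the 0/1 adjacency by the corresponding node's
#' degree, giving the column-stochastic transition matrix `M` of a simple
#' random walk: `M[i, j]` is the probability of stepping to node `i` from
#' node `j`. Zero-degree nodes have no outgoing distribution; remove them
#' first with [restrict_to_components()].
#'
#' @param net A [cnc_network()].
#' @return A sparse column-stochastic `Matrix` with node ids as dimnames.
#' @export
column_normalize <- function(net) {
  a <- adjacency_matrix(net)
  deg <- Matrix::colSums(a)
  if (any(deg == 0))
    stop("zero-degree node(s) present (run restrict_to_components first): ",
         paste(utils::head(names(deg)[deg == 0], 5L), collapse = ", "))
  m <- a %*% Matrix::Diagonal(x = 1 / deg)
  dimnames(m) <- dimnames(a)
  m
}

#' Random walk with restart from a seed lncRNA set
#'
#' Iterates `p_{t+1} = (1 - r) M p_t + r p_0`, where `M` is the
#' column-normalized adjacency and `p_0` places equal mass on every mapped
#' seed lncRNA, until the L1 change between successive iterates falls below
#' `cfg$tolerance`. The steady state measures each node's network proximity
#' to the seed set: the restart pins probability near the seeds while the
#' walk diffuses it along edges. Seeds that are not lncRNA nodes of the
#' network are dropped with a warning and counted in `n_dropped`.
#'
#' @param net A [cnc_network()] without zero-degree nodes.
#' @param seeds Character vector of seed lncRNA identifiers.
#' @param cfg A [propagation_config()]; default restart probability 0.7,
#'   L1 tolerance 1e-10.
#' @return Object of class `rwr_result` with elements `steady_state` (named
#'   probability vector over all nodes), `seed_ids` (mapped seeds),
#'   `n_dropped`, `iterations`, `residual` and `config`.
#' @export
rwr <- function(net, seeds, cfg = propagation_config()) {
  stopifnot(inherits(net, "cnc_network"),
            inherits(cfg, "propagation_config"))
  seeds <- unique(as.character(seeds))
  lnc <- net$nodes$gene_id[net$nodes$biotype == "lncRNA"]
  mapped <- intersect(seeds, lnc)
  dropped <- setdiff(seeds, mapped)
  if (length(mapped) == 0L)
    stop("no seed maps to a lncRNA node of the network")
  if (length(dropped) > 0L)
    warning(length(dropped), " seed(s) not found among network lncRNAs ",
            "and dropped")

  m <- column_normalize(net)
  ids <- rownames(m)
  p0 <- stats::setNames(numeric(length(ids)), ids)
  p0[mapped] <- 1 / length(mapped)

  r <- cfg$restart_probability
  p <- p0
  resid <- Inf
  iter <- 0L
  while (iter < cfg$max_iterations) {
    p_new <- as.numeric((1 - r) * (m %*% p)) + r * p0
    resid <- sum(abs(p_new - p))
    p <- p_new
    iter <- iter + 1L
    if (resid < cfg$tolerance) break
  }
  if (resid >= cfg$tolerance)
    stop(sprintf(
      "random walk did not converge in %d iterations (last L1 residual %g)",
      cfg$max_iterations, resid))
  structure(list(steady_state = stats::setNames(p, ids),
                 seed_ids = mapped,
                 n_dropped = length(dropped),
                 iterations = iter,
                 residual = resid,
                 config = cfg),
            class = "rwr_result")
}

#' @export
print.rwr_result <- function(x, ...) {
  cat("<rwr_result>", length(x$steady_state), "nodes,",
      length(x$seed_ids), "seeds (", x$n_dropped, "dropped ),",
      x$iterations, "iterations, L1 residual", format(x$residual), "\n")
  if (!is.null(x$ranked_list))
    cat("  ranked list:", length(x$ranked_list), "coding genes, top:",
        paste(utils::head(x$ranked_list, 3L), collapse = ", "), "...\n")
  invisible(x)
}

#' Propagation scores and the ranked coding-gene list
#'
#' Assigns each protein-coding gene the square root of its steady-state
#' probability (its *propagation score* `t_j`) and orders all coding genes
#' of the network by descending score into the ranked list `L` used for
#' pathway scoring. Ties are broken by gene identifier (ascending) so core
#' gene sets are reproducible.
#'
#' @param result An `rwr_result` from [rwr()].
#' @param net The [cnc_network()] the walk was run on.
#' @return The `rwr_result` augmented with `propagation_scores` (named,
#'   in rank order) and `ranked_list`.
#' @export
rank_coding_genes <- function(result, net) {
  stopifnot(inherits(result, "rwr_result"), inherits(net, "cnc_network"))
  coding <- net$nodes$gene_id[net$nodes$biotype == "coding"]
  p <- result$steady_state[coding]
  t_j <- sqrt(p)
  ord <- order(-t_j, coding, method = "radix")
  result$propagation_scores <- stats::setNames(unname(t_j[ord]), coding[ord])
  result$ranked_list <- coding[ord]
  result
}
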