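#' Construct a coding/non-coding gene correlation (CNC) network
#'
#' Low-level constructor validating the node and edge tables. Most users
#' build networks with [build_network()] or read them with [read_network()].
#'
#' @param nodes data.frame with columns `gene_id`, `biotype`
#'   (`"lncRNA"`/`"coding"`).
#' @param edges data.frame with columns `gene_a`, `gene_b`, `provenance`
#'   (`"coexpression"`, `"ppi"` or `"both"`) and optionally `sign`
#'   (+1 / -1 / NA).
#' @return An object of class `cnc_network`.
#' @export
cnc_network <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges),
            all(c("gene_id", "biotype") %in% names(nodes)),
            all(c("gene_a", "gene_b") %in% names(edges)))
  nodes$gene_id <- as.character(nodes$gene_id)
  nodes$biotype <- as.character(nodes$biotype)
  if (anyDuplicated(nodes$gene_id)) stop("duplicated node identifiers")
  bad <- setdiff(unique(nodes$biotype), c("lncRNA", "coding"))
  if (length(bad)) stop("unknown biotype: ", paste(bad, collapse = ", "))

  if (is.null(edges$provenance))
    edges$provenance <- rep("coexpression", nrow(edges))
  if (is.null(edges$sign)) edges$sign <- rep(NA_integer_, nrow(edges))
  pc <- canonical_pairs(edges$gene_a, edges$gene_b)
  edges$gene_a <- pc$gene_a; edges$gene_b <- pc$gene_b
  edges <- edges[, c("gene_a", "gene_b", "provenance", "sign")]
  if (any(edges$gene_a == edges$gene_b)) stop("self-loop edge present")
  key <- paste(edges$gene_a, edges$gene_b)
  if (anyDuplicated(key)) stop("duplicated edge present")
  bad <- setdiff(unique(edges$provenance), c("coexpression", "ppi", "both"))
  if (length(bad)) stop("unknown provenance: ", paste(bad, collapse = ", "))
  missing <- setdiff(unique(c(edges$gene_a, edges$gene_b)), nodes$gene_id)
  if (length(missing))
    stop("edge endpoint(s) not declared as nodes: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "cnc_network")
}

#' @export
print.cnc_network <- function(x, ...) {
  cat("<cnc_network>", nrow(x$nodes), "nodes (",
      sum(x$nodes$biotype == "lncRNA"), "lncRNA /",
      sum(x$nodes$biotype == "coding"), "coding ),",
      nrow(x$edges), "edges (",
      sum(x$edges$provenance == "coexpression"), "coexpression /",
      sum(x$edges$provenance == "ppi"), "ppi /",
      sum(x$edges$provenance == "both"), "both )\n")
  invisible(x)
}

#' Merge consensus co-expression edges with protein-protein interactions
#'
#' Takes the union of the two edge sets; a pair found in both is tagged with
#' provenance `"both"`. Protein-protein interaction (PPI) nodes without a
#' declared biotype default to `"coding"`; a lncRNA appearing in a PPI edge
#' is an error, since PPIs connect proteins. Declared nodes that end up with
#' no edge are removed.
#'
#' @param coexpr data.frame of consensus co-expression pairs
#'   (columns `gene_a`, `gene_b`, optionally `sign`), e.g. from
#'   [consensus_edges()]. May have zero rows.
#' @param ppi data.frame of PPI pairs (columns `gene_a`, `gene_b`).
#'   May have zero rows.
#' @param node_biotypes Named character vector `gene_id -> biotype`. Every
#'   co-expression node must be present; PPI-only nodes may be omitted.
#' @return A [cnc_network()].
#' @export
build_network <- function(coexpr, ppi, node_biotypes) {
  norm_pairs <- function(df, keep_sign = FALSE) {
    if (is.null(df) || nrow(df) == 0L)
      return(data.frame(gene_a = character(), gene_b = character(),
                        sign = integer(), stringsAsFactors = FALSE))
    pc <- canonical_pairs(df$gene_a, df$gene_b)
    s <- if (keep_sign && !is.null(df$sign)) as.integer(df$sign)
         else rep(NA_integer_, nrow(df))
    out <- data.frame(gene_a = pc$gene_a, gene_b = pc$gene_b, sign = s,
                      stringsAsFactors = FALSE)
    out <- out[out$gene_a != out$gene_b, ]
    key <- paste(out$gene_a, out$gene_b)
    if (anyDuplicated(key)) {
      if (keep_sign) {
        n_signs <- tapply(out$sign, key, function(s) length(unique(s)))
        if (any(n_signs > 1, na.rm = TRUE))
          warning("pair(s) with conflicting signs; first occurrence kept")
      }
      out <- out[!duplicated(key), ]
    }
    out
  }
  ce <- norm_pairs(coexpr, keep_sign = TRUE)
  pp <- norm_pairs(ppi)

  bt <- node_biotypes
  ce_nodes <- unique(c(ce$gene_a, ce$gene_b))
  missing_bt <- setdiff(ce_nodes, names(bt))
  if (length(missing_bt))
    stop("biotype unknown for co-expression node(s): ",
         paste(utils::head(missing_bt, 5L), collapse = ", "))
  pp_nodes <- unique(c(pp$gene_a, pp$gene_b))
  lnc_in_ppi <- pp_nodes[!is.na(bt[pp_nodes]) & bt[pp_nodes] == "lncRNA"]
  if (length(lnc_in_ppi))
    stop("lncRNA node(s) in PPI edges (PPIs connect proteins): ",
         paste(utils::head(lnc_in_ppi, 5L), collapse = ", "))
  new_pp <- setdiff(pp_nodes, names(bt))
  if (length(new_pp)) bt <- c(bt, stats::setNames(rep("coding",
                                                      length(new_pp)),
                                                  new_pp))

  ce_key <- paste(ce$gene_a, ce$gene_b)
  pp_key <- paste(pp$gene_a, pp$gene_b)
  shared <- intersect(ce_key, pp_key)
  ce$provenance <- ifelse(ce_key %in% shared, "both", "coexpression")
  pp_only <- pp[!(pp_key %in% shared), , drop = FALSE]
  pp_only$provenance <- if (nrow(pp_only)) "ppi" else character(0)
  edges <- rbind(ce[, c("gene_a", "gene_b", "provenance", "sign")],
                 pp_only[, c("gene_a", "gene_b", "provenance", "sign")])
  if (nrow(edges) == 0L) stop("no edges: cannot build an empty network")
  used <- unique(c(edges$gene_a, edges$gene_b))
  nodes <- data.frame(gene_id = used, biotype = unname(bt[used]),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$gene_id), ]
  cnc_network(nodes, edges[order(edges$gene_a, edges$gene_b), ])
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("gene_a", "gene_b")],
                                directed = FALSE,
                                vertices = net$nodes$gene_id)
}

#' Symmetric 0/1 adjacency matrix of a CNC network
#'
#' @param net A [cnc_network()].
#' @return A sparse symmetric `Matrix` with node identifiers as dimnames.
#' @export
adjacency_matrix <- function(net) {
  ids <- net$nodes$gene_id
  i <- match(net$edges$gene_a, ids)
  j <- match(net$edges$gene_b, ids)
  a <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = 1, dims = c(length(ids), length(ids)),
                            dimnames = list(ids, ids))
  a
}

#' Drop isolated nodes and label connected components
#'
#' @param net A [cnc_network()].
#' @return List with `network` (isolated nodes removed), `membership`
#'   (named integer component label per kept node), `n_components` and
#'   `largest_size`.
#' @export
restrict_to_components <- function(net) {
  stopifnot(inherits(net, "cnc_network"))
  if (nrow(net$edges) == 0L) stop("network has no edges")
  used <- unique(c(net$edges$gene_a, net$edges$gene_b))
  nodes <- net$nodes[net$nodes$gene_id %in% used, , drop = FALSE]
  out <- cnc_network(nodes, net$edges)
  comp <- igraph::components(as_igraph(out))
  list(network = out,
       membership = comp$membership,
       n_components = as.integer(comp$no),
       largest_size = as.integer(max(comp$csize)))
}

#' Power-law fit of the degree distribution
#'
#' Least-squares line on `(log k, log P(k))` over degrees with nonzero
#' empirical frequency; the exponent `gamma` is the negative slope. A
#' scale-free network shows an approximately linear log-log degree
#' distribution (`P(k) ~ k^-gamma`), the structural sanity check applied to
#' CNC networks.
#'
#' @param net A [cnc_network()].
#' @return List of class `powerlaw_fit`: `gamma`, `r_squared`,
#'   `degree_histogram` (data.frame `degree`, `count`).
#' @export
degree_powerlaw_fit <- function(net) {
  stopifnot(inherits(net, "cnc_network"))
  deg <- igraph::degree(as_igraph(net))
  deg <- deg[deg > 0]
  tab <- table(deg)
  k <- as.numeric(names(tab))
  if (length(k) < 2L)
    stop("need at least 2 distinct degree values for a power-law fit")
  pk <- as.numeric(tab) / sum(tab)
  fit <- stats::lm(log(pk) ~ log(k))
  structure(list(gamma = -unname(stats::coef(fit)[2L]),
                 r_squared = summary(fit)$r.squared,
                 degree_histogram = data.frame(degree = k,
                                               count = as.integer(tab))),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> gamma = %.3f, R-squared = %.4f (%d degrees)\n",
              x$gamma, x$r_squared, nrow(x$degree_histogram)))
  invisible(x)
}
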