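# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's own code paths: dense linear algebra for the random walk, a
# hand-rolled breadth-first search for components, and position-by-position
# summation for the KS statistic.

make_net <- function(edges_df, biotype = NULL) {
  ids <- sort(unique(c(edges_df$gene_a, edges_df$gene_b)))
  if (is.null(biotype)) biotype <- rep("coding", length(ids))
  cnc_network(data.frame(gene_id = ids, biotype = biotype,
                         stringsAsFactors = FALSE),
              edges_df)
}

path_net <- function() {
  make_net(data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                      stringsAsFactors = FALSE),
           biotype = c("lncRNA", "coding", "coding"))
}

triangle_net <- function() {
  make_net(data.frame(gene_a = c("A", "A", "B"), gene_b = c("B", "C", "C"),
                      stringsAsFactors = FALSE),
           biotype = c("lncRNA", "coding", "coding"))
}

# Random connected network: random recursive tree plus extra edges, so
# connectivity holds by construction (no rejection sampling).
random_connected_net <- function(n, extra = n %/% 2,
                                 n_lnc = max(1L, n %/% 5L)) {
  parents <- vapply(seq_len(n - 1L) + 1L,
                    function(i) sample.int(i - 1L, 1L), 1L)
  e1 <- c(2:n, sample.int(n, extra, replace = TRUE))
  e2 <- c(parents, sample.int(n, extra, replace = TRUE))
  a <- pmin(e1, e2); b <- pmax(e1, e2)
  keep <- a != b
  ids <- sprintf("N%03d", seq_len(n))
  df <- unique(data.frame(gene_a = ids[a[keep]], gene_b = ids[b[keep]],
                          stringsAsFactors = FALSE))
  biotype <- rep("coding", n)
  biotype[sample.int(n, n_lnc)] <- "lncRNA"
  make_net(df, biotype)
}

# Direct linear solve of the restart-walk fixed point:
# p = r (I - (1-r) M)^{-1} p0
rwr_dense_oracle <- function(net, seeds, r) {
  a <- as.matrix(adjacency_matrix(net))
  m <- sweep(a, 2L, colSums(a), "/")
  ids <- colnames(a)
  p0 <- stats::setNames(numeric(length(ids)), ids)
  p0[seeds] <- 1 / length(seeds)
  stats::setNames(drop(r * solve(diag(length(ids)) - (1 - r) * m) %*% p0),
                  ids)
}

# Unweighted KS enrichment: max over positions of the difference between
# the hit and miss empirical fractions, each computed by direct summation.
ks_unweighted_oracle <- function(ranked_ids, pathway_genes) {
  hits <- ranked_ids %in% pathway_genes
  n <- length(hits); nh <- sum(hits); nm <- n - nh
  max(vapply(seq_len(n), function(i)
    sum(hits[seq_len(i)]) / nh - sum(!hits[seq_len(i)]) / nm, 0))
}

# Connected-component count by hand-rolled BFS over an adjacency list.
bfs_component_count <- function(net) {
  ids <- net$nodes$gene_id
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (k in seq_len(nrow(net$edges))) {
    a <- net$edges$gene_a[k]; b <- net$edges$gene_b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- stats::setNames(rep(FALSE, length(ids)), ids)
  n_comp <- 0L
  for (s in ids) {
    if (seen[s]) next
    n_comp <- n_comp + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- adj[[v]]
      new <- nb[!seen[nb]]
      seen[new] <- TRUE
      queue <- c(queue, new)
    }
  }
  n_comp
}

toy_scores <- function() {
  stats::setNames(c(0.5, 0.4, 0.3, 0.2, 0.1), paste0("g", 1:5))
}
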