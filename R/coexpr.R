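#' Expression-level gene filter
#'
#' Retains genes with mean FPKM above `min_mean_fpkm` (strict) and an FPKM
#' variance ranked in the top `variance_keep_fraction` of all genes in the
#' dataset. Both filters are evaluated on the full gene set, then
#' intersected; ties at the variance cutoff are kept, and the input gene
#' order is preserved.
#'
#' @param dataset An [expression_dataset()].
#' @param min_mean_fpkm Mean-FPKM threshold (genes must exceed it). Default 1.
#' @param variance_keep_fraction Fraction of genes retained by the variance
#'   rank filter. Default 0.75 (the bottom quartile by variance is dropped).
#' @return A filtered `expression_dataset`.
#' @export
filter_genes <- function(dataset, min_mean_fpkm = 1,
                         variance_keep_fraction = 0.75) {
  stopifnot(inherits(dataset, "expression_dataset"))
  x <- dataset$fpkm
  if (nrow(x) == 0L) stop("dataset is empty")
  means <- rowMeans(x)
  vars <- apply(x, 1L, stats::var)
  n_drop <- floor((1 - variance_keep_fraction) * nrow(x))
  # ties.method = "max": genes tied with the cutoff value all survive
  keep_var <- rank(vars, ties.method = "max") > n_drop
  keep <- means > min_mean_fpkm & keep_var
  if (!any(keep)) stop("no genes pass filters")
  expression_dataset(dataset$dataset_id,
                     x[keep, , drop = FALSE],
                     dataset$biotype[keep])
}

#' Fisher z transform of a Pearson correlation
#'
#' `z = 0.5 * (ln(1 + r) - ln(1 - r))`, the variance-stabilizing transform
#' whose sampling distribution is approximately normal with standard error
#' `1/sqrt(N - 3)` for a sample of size `N`.
#'
#' @param r Correlation coefficient(s), strictly inside (-1, 1).
#' @return The transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1))
    stop("degenerate correlation |r| >= 1 (duplicated expression vectors?)")
  0.5 * (log1p(r) - log1p(-r))
}

#' Per-dataset co-expression extraction
#'
#' Computes the Pearson correlation for every gene pair, Fisher-z transforms
#' it and scales by the standard error `1/sqrt(N - 3)`, standardizes each
#' gene's pair z-statistics to zero mean and unit variance, converts the
#' standardized scores to two-sided normal p-values and Bonferroni-adjusts
#' them within each gene's family of pairs. A pair is flagged co-expressed
#' when its |r| ranks within the top `rank_fraction` of pairs for the
#' endpoint genes *and* the endpoint-adjusted p-values fall below `alpha`.
#' With the default `endpoint_rule = "both"` each condition must hold from
#' both endpoints; `"either"` relaxes this to one endpoint.
#'
#' Genes with zero expression variance cannot be correlated and are removed
#' up front with a warning.
#'
#' @param dataset A gene-filtered [expression_dataset()].
#' @param rank_fraction Per-gene |r| rank cutoff (default 0.001, i.e. the
#'   top/bottom 0.1 percent of a gene's correlations). Ties at the rank
#'   boundary are included.
#' @param alpha Adjusted p-value threshold. Default 0.01.
#' @param endpoint_rule `"both"` (default) or `"either"`: how the per-endpoint
#'   rank and significance conditions are combined.
#' @return A data.frame of flagged pairs with columns `gene_a`, `gene_b`
#'   (lexicographic pair order), `r`, `z` (Fisher transform), `sign`,
#'   `z_std_a`, `z_std_b`, `p_adj_a`, `p_adj_b`, `p_adj` (the binding one),
#'   `rank_pass_a`, `rank_pass_b`.
#' @export
dataset_coexpression <- function(dataset, rank_fraction = 0.001,
                                 alpha = 0.01,
                                 endpoint_rule = c("both", "either")) {
  stopifnot(inherits(dataset, "expression_dataset"))
  endpoint_rule <- match.arg(endpoint_rule)
  n_samp <- dataset$n_samples
  if (n_samp <= 3L) stop("standard error undefined for N <= 3 samples")

  x <- dataset$fpkm
  v <- apply(x, 1L, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " constant-expression gene(s) skipped: ",
            paste(utils::head(rownames(x)[v == 0], 5L), collapse = ", "))
    x <- x[v > 0, , drop = FALSE]
  }
  g <- nrow(x)
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      r = numeric(), z = numeric(), sign = integer(),
                      z_std_a = numeric(), z_std_b = numeric(),
                      p_adj_a = numeric(), p_adj_b = numeric(),
                      p_adj = numeric(),
                      rank_pass_a = logical(), rank_pass_b = logical(),
                      stringsAsFactors = FALSE)
  if (g < 2L) return(empty)

  r_mat <- stats::cor(t(x))
  off <- abs(r_mat) >= 1 & row(r_mat) != col(r_mat)
  if (any(off)) {
    warning("perfectly correlated gene pair(s); correlations clamped")
    r_mat[off] <- sign(r_mat[off]) * (1 - 1e-10)
  }
  z_mat <- fisher_z(r_mat * (row(r_mat) != col(r_mat)))  # diag zeroed
  z_mat <- z_mat * sqrt(n_samp - 3)                      # scale by 1/SE
  diag(z_mat) <- NA_real_

  # standardize each gene's (row's) pair statistics to mean 0, sd 1
  mu <- rowMeans(z_mat, na.rm = TRUE)
  sd_row <- apply(z_mat, 1L, stats::sd, na.rm = TRUE)
  sd_row[sd_row == 0] <- NA_real_
  z_std <- (z_mat - mu) / sd_row

  p_adj <- 2 * stats::pnorm(-abs(z_std)) * (g - 1)
  p_adj[p_adj > 1] <- 1  # (pmin would drop the matrix dims)

  # per-gene |r| rank rule: a pair passes from endpoint i when its |r| is at
  # least the k-th largest among gene i's pairs (ties inclusive)
  abs_r <- abs(r_mat)
  diag(abs_r) <- NA_real_
  k <- max(1L, ceiling(rank_fraction * (g - 1L)))
  thr <- apply(abs_r, 1L, function(row)
    sort(row, decreasing = TRUE, na.last = NA)[min(k, sum(!is.na(row)))])
  rank_pass <- abs_r >= thr  # row i: pass from endpoint i

  idx <- which(upper.tri(r_mat), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  pa_i <- p_adj[cbind(i, j)]   # endpoint = gene i
  pa_j <- p_adj[cbind(j, i)]   # endpoint = gene j
  rp_i <- rank_pass[cbind(i, j)]
  rp_j <- rank_pass[cbind(j, i)]
  sig_i <- !is.na(pa_i) & pa_i < alpha
  sig_j <- !is.na(pa_j) & pa_j < alpha
  flagged <- if (endpoint_rule == "both")
    rp_i & rp_j & sig_i & sig_j
  else
    (rp_i | rp_j) & (sig_i | sig_j)
  if (!any(flagged)) return(empty)

  sel <- which(flagged)
  ids <- rownames(x)
  pc <- canonical_pairs(ids[i[sel]], ids[j[sel]])
  swapped <- ids[i[sel]] > ids[j[sel]]
  first <- function(a, b) ifelse(swapped, b, a)
  r_sel <- r_mat[cbind(i[sel], j[sel])]
  out <- data.frame(gene_a = pc$gene_a, gene_b = pc$gene_b,
                    r = r_sel, z = fisher_z(r_sel),
                    sign = as.integer(sign(r_sel)),
                    z_std_a = first(z_std[cbind(i[sel], j[sel])],
                                    z_std[cbind(j[sel], i[sel])]),
                    z_std_b = first(z_std[cbind(j[sel], i[sel])],
                                    z_std[cbind(i[sel], j[sel])]),
                    p_adj_a = first(pa_i[sel], pa_j[sel]),
                    p_adj_b = first(pa_j[sel], pa_i[sel]),
                    rank_pass_a = first(rp_i[sel], rp_j[sel]),
                    rank_pass_b = first(rp_j[sel], rp_i[sel]),
                    stringsAsFactors = FALSE)
  out$p_adj <- if (endpoint_rule == "both")
    pmax(out$p_adj_a, out$p_adj_b) else pmin(out$p_adj_a, out$p_adj_b)
  out[order(out$gene_a, out$gene_b), ]
}

#' Cross-dataset consensus co-expression edges
#'
#' A pair becomes a consensus edge when it was flagged co-expressed with the
#' same correlation sign in at least `min_support` datasets. Positive and
#' negative flags for the same pair are counted separately; a direction that
#' never reaches `min_support` is dropped.
#'
#' @param per_dataset_edges List of per-dataset flagged-pair data.frames as
#'   returned by [dataset_coexpression()] (columns `gene_a`, `gene_b` and
#'   either `sign` or `r`).
#' @param min_support Minimum number of same-direction datasets. Default 3.
#' @return data.frame with columns `gene_a`, `gene_b`, `sign`, `support`.
#' @export
consensus_edges <- function(per_dataset_edges, min_support = 3L) {
  stopifnot(is.list(per_dataset_edges), length(per_dataset_edges) >= 1L)
  recs <- lapply(per_dataset_edges, function(df) {
    if (nrow(df) == 0L) return(NULL)
    s <- if ("sign" %in% names(df)) df$sign else sign(df$r)
    pc <- canonical_pairs(df$gene_a, df$gene_b)
    unique(data.frame(gene_a = pc$gene_a, gene_b = pc$gene_b,
                      sign = as.integer(s), stringsAsFactors = FALSE))
  })
  recs <- do.call(rbind, recs)
  out <- data.frame(gene_a = character(), gene_b = character(),
                    sign = integer(), support = integer(),
                    stringsAsFactors = FALSE)
  if (is.null(recs) || nrow(recs) == 0L) return(out)
  key <- paste(recs$gene_a, recs$gene_b, recs$sign, sep = "\r")
  tab <- table(key)
  keep <- names(tab)[tab >= min_support]
  if (length(keep) == 0L) return(out)
  parts <- strsplit(keep, "\r", fixed = TRUE)
  out <- data.frame(gene_a = vapply(parts, `[`, "", 1L),
                    gene_b = vapply(parts, `[`, "", 2L),
                    sign = as.integer(vapply(parts, `[`, "", 3L)),
                    support = as.integer(tab[keep]),
                    stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b, out$sign), ]
}
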