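#' Construct an expression dataset
#'
#' Bundles one study's FPKM matrix (genes x samples) with per-gene biotypes.
#' The sample count is the `N` used by the Fisher-z standard error
#' `1/sqrt(N - 3)` during co-expression extraction, and at least six samples
#' are required for a correlation estimate worth keeping.
#'
#' @param dataset_id Character label for the dataset.
#' @param fpkm Numeric matrix of non-negative FPKM values, genes in rows
#'   (rownames are the gene identifiers), samples in columns.
#' @param biotype Character vector, one of `"lncRNA"` or `"coding"` per gene,
#'   in row order of `fpkm` (or named by gene identifier).
#' @return An object of class `expression_dataset`: a list with elements
#'   `dataset_id`, `fpkm`, `biotype` and `n_samples`.
#' @examples
#' m <- matrix(rexp(60), nrow = 10,
#'             dimnames = list(paste0("G", 1:10), NULL))
#' ds <- expression_dataset("toy", m, rep(c("lncRNA", "coding"), 5))
#' @export
expression_dataset <- function(dataset_id, fpkm, biotype) {
  stopifnot(is.matrix(fpkm), is.numeric(fpkm))
  ids <- rownames(fpkm)
  if (is.null(ids) || anyDuplicated(ids))
    stop("fpkm must have unique gene identifiers as rownames")
  if (ncol(fpkm) < 6L)
    stop("expression dataset must have at least six samples, got ",
         ncol(fpkm))
  if (any(fpkm < 0))
    stop("FPKM values must be non-negative")
  if (!is.null(names(biotype))) biotype <- biotype[ids]
  biotype <- as.character(biotype)
  if (length(biotype) != nrow(fpkm) || any(is.na(biotype)))
    stop("biotype must be given for every gene")
  bad <- setdiff(unique(biotype), c("lncRNA", "coding"))
  if (length(bad))
    stop("unknown biotype: ", paste(bad, collapse = ", "))
  structure(list(dataset_id = as.character(dataset_id),
                 fpkm = fpkm,
                 biotype = stats::setNames(biotype, ids),
                 n_samples = ncol(fpkm)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset>", x$dataset_id, "\n",
      nrow(x$fpkm), "genes (",
      sum(x$biotype == "lncRNA"), "lncRNA /",
      sum(x$biotype == "coding"), "coding ) x",
      x$n_samples, "samples\n")
  invisible(x)
}

#' Random walk with restart settings
#'
#' @param restart_probability Probability `r` in `(0, 1]` of returning to the
#'   seed distribution at each step. Default 0.7.
#' @param tolerance L1 convergence threshold for the power iteration.
#'   Default 1e-10.
#' @param max_iterations Safety cap on iterations. Default 10000.
#' @return A `propagation_config` list.
#' @export
propagation_config <- function(restart_probability = 0.7,
                               tolerance = 1e-10,
                               max_iterations = 10000L) {
  if (!(restart_probability > 0 && restart_probability <= 1))
    stop("restart_probability must be in (0, 1]")
  if (tolerance <= 0) stop("tolerance must be positive")
  if (max_iterations < 1) stop("max_iterations must be at least 1")
  structure(list(restart_probability = restart_probability,
                 tolerance = tolerance,
                 max_iterations = as.integer(max_iterations)),
            class = "propagation_config")
}

#' Construct a pathway gene set
#'
#' @param pathway_id Identifier (first GMT field).
#' @param name Free-text description (second GMT field).
#' @param genes Character vector of member protein-coding gene identifiers.
#' @return A `pathway_gene_set` list.
#' @export
pathway_gene_set <- function(pathway_id, name, genes) {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("pathway '", pathway_id, "' has no genes")
  if (anyDuplicated(genes)) {
    warning("pathway '", pathway_id, "': duplicated gene ids removed")
    genes <- unique(genes)
  }
  structure(list(pathway_id = as.character(pathway_id),
                 name = as.character(name),
                 genes = genes),
            class = "pathway_gene_set")
}

# Canonical unordered-pair ordering: smaller identifier first. Keeps pair
# tables set-like so merges and consensus counting are well defined.
canonical_pairs <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  list(gene_a = a, gene_b = b)
}
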