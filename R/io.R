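# All interchange formats are plain text: tab-delimited with a header row
# (expression, networks, results), GMT for pathways, one-id-per-line seed
# lists, JSON for run manifests.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read an expression dataset from TSV
#'
#' Expected layout: header row; first column the gene identifier, second
#' column the biotype (`lncRNA`/`coding`), remaining columns per-sample
#' FPKM values.
#'
#' @param path File path.
#' @param dataset_id Dataset label; defaults to the file name without
#'   extension.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path,
                            dataset_id = sub("\\.[^.]*$", "",
                                             basename(path))) {
  df <- read_tsv(path)
  if (ncol(df) < 3L)
    stop("expression file needs gene id, biotype and sample columns: ", path)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  expression_dataset(dataset_id, m, as.character(df[[2L]]))
}

#' Write an expression dataset to TSV
#'
#' @param dataset An [expression_dataset()].
#' @param path File path.
#' @export
write_expression <- function(dataset, path) {
  df <- data.frame(gene_id = rownames(dataset$fpkm),
                   biotype = unname(dataset$biotype),
                   dataset$fpkm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read pathway gene sets from a GMT file
#'
#' One pathway per line: identifier, description and member genes, all
#' tab-separated. Duplicate gene ids within a line are removed with a
#' warning; lines with fewer than three fields or no genes are errors.
#'
#' @param path File path.
#' @return List of [pathway_gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, " (fewer than 3 tab-separated fields)")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L)
      stop("malformed GMT line ", i, " (empty gene list)")
    if (anyDuplicated(genes))
      warning("GMT line ", i, " ('", f[1L], "'): duplicate gene ids removed")
    out[[i]] <- pathway_gene_set(f[1L], f[2L],
                                 suppressWarnings(unique(genes)))
  }
  out
}

#' Write pathway gene sets to a GMT file
#'
#' @param pathways List of [pathway_gene_set()] objects.
#' @param path File path.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(pathways, function(p)
    paste(c(p$pathway_id, p$name, p$genes), collapse = "\t"), "")
  writeLines(lines, path)
}

#' Read a CNC network from its edge and node files
#'
#' Node file: TSV with columns `gene_id`, `biotype`. Edge file: TSV with
#' columns `gene_a`, `gene_b`, `provenance`, `sign`. Edges referencing
#' undeclared nodes or unknown biotypes are errors.
#'
#' @param edge_path,node_path File paths.
#' @return A [cnc_network()].
#' @export
read_network <- function(edge_path, node_path) {
  nodes <- read_tsv(node_path)
  edges <- read_tsv(edge_path)
  if (!is.null(edges$sign)) edges$sign <- as.integer(edges$sign)
  cnc_network(nodes, edges)
}

#' Write a CNC network to edge and node files
#'
#' @param net A [cnc_network()].
#' @param edge_path,node_path File paths.
#' @export
write_network <- function(net, edge_path, node_path) {
  write_tsv(net$edges, edge_path)
  write_tsv(net$nodes, node_path)
}

#' Read a seed lncRNA list
#'
#' One identifier per line; blank lines and `#` comments are ignored.
#'
#' @param path File path.
#' @return Character vector of seed identifiers.
#' @export
read_seeds <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}

#' Write pathway results to TSV
#'
#' Columns: `pathway_id`, `name`, `size`, `es`, `p_value`, `fdr`,
#' `peak_index`, `core_genes` (semicolon-separated, rank order). Missing
#' p-values (permutations disabled) are written as empty fields.
#'
#' @param results Results data.frame from [lnc_pathways()].
#' @param path File path.
#' @export
write_results <- function(results, path) {
  cols <- c("pathway_id", "name", "size", "es", "p_value", "fdr",
            "peak_index", "core_genes")
  write_tsv(as.data.frame(results)[, cols], path)
}

#' Read pathway results written by [write_results()]
#'
#' @param path File path.
#' @return data.frame; empty p-value fields become `NA`.
#' @export
read_results <- function(path) {
  df <- read_tsv(path)
  for (col in c("size", "peak_index")) df[[col]] <- as.integer(df[[col]])
  for (col in c("es", "p_value", "fdr")) df[[col]] <- as.numeric(df[[col]])
  df$core_genes <- as.character(df$core_genes)
  df$core_genes[is.na(df$core_genes)] <- ""
  df$name <- as.character(df$name)
  df
}

#' Write a JSON run manifest
#'
#' Records everything needed to replay an analysis: input paths, all
#' numeric settings, the RNG seed, the dropped-seed count and the package
#' version.
#'
#' @param manifest Named list.
#' @param path File path.
#' @export
write_manifest <- function(manifest, path) {
  manifest$software <- "lncprop"
  manifest$version <- as.character(utils::packageVersion("lncprop"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
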