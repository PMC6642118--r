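# Downstream analyses on the gene-level expression matrix, plus the
# literature-driven gene network overlapped on a scored interactome.

#' Principal component analysis of samples
#'
#' Samples are projected onto the principal axes of the gene-mean-centred
#' expression matrix (singular value decomposition; genes are not
#' rescaled -- z-scoring is a separate explicit step). Missing values are
#' imputed to the gene mean before the decomposition and the imputation
#' count is reported. The sign of each component is fixed by making its
#' largest-magnitude gene loading positive, so scores are reproducible
#' across runs and sample orderings.
#'
#' @param matrix numeric matrix, genes x samples.
#' @param k number of components to keep (at most `min(genes, samples)`).
#' @return object of class `pca_result`: `scores` (samples x k),
#'   `loadings` (genes x k), `explained_ratio` (length k; fractions of
#'   the total variance over all computed components), `k`, `n_imputed`.
#' @export
expr_pca <- function(matrix, k = 2L) {
  stopifnot(ncol(matrix) >= 2L)
  if (k > min(dim(matrix)))
    stop("k exceeds min(genes, samples) = ", min(dim(matrix)))
  n_imputed <- sum(is.na(matrix))
  if (n_imputed > 0L) {
    mu <- rowMeans(matrix, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(matrix), arr.ind = TRUE)
    matrix[idx] <- mu[idx[, 1L]]
  }
  pc <- stats::prcomp(t(matrix), center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    l[[which.max(abs(l))]] < 0
  }, TRUE)
  pc$rotation[, flip] <- -pc$rotation[, flip]
  pc$x[, flip] <- -pc$x[, flip]
  ratio <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 explained_ratio = ratio[seq_len(k)],
                 explained_ratio_all = ratio,
                 center = pc$center,
                 k = as.integer(k), n_imputed = n_imputed),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA: ", nrow(x$scores), " samples, k = ", x$k,
      "; explained: ", paste(sprintf("%.1f%%", 100 * x$explained_ratio),
                             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Most variable genes
#'
#' Genes sorted by their across-sample variance, descending; ties broken
#' by gene name ascending. Returns the first `min(n, genes)` names.
#' @export
top_variable_genes <- function(matrix, n) {
  stopifnot(n >= 1)
  v <- apply(matrix, 1L, stats::var, na.rm = TRUE)
  v[is.na(v)] <- 0
  ord <- order(-v, rownames(matrix))
  rownames(matrix)[ord][seq_len(min(n, nrow(matrix)))]
}

#' Row-wise z-scores
#'
#' Each row is centred by its mean and scaled by its sample standard
#' deviation. Rows with zero variance or fewer than two observed values
#' become all-zero with a warning; missing cells stay missing.
#' @export
zscore_rows <- function(matrix) {
  mu <- rowMeans(matrix, na.rm = TRUE)
  sd <- apply(matrix, 1L, stats::sd, na.rm = TRUE)
  n_obs <- rowSums(!is.na(matrix))
  degenerate <- n_obs < 2L | is.na(sd) | sd == 0
  if (any(degenerate))
    warning(sum(degenerate), " constant or under-observed row(s) set to zero")
  out <- (matrix - mu) / ifelse(degenerate, 1, sd)
  out[degenerate, ] <- 0
  out[is.na(matrix)] <- NA_real_  # missing cells stay missing
  out
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the sample profiles (Euclidean distance,
#' complete linkage by default). Samples are sorted by name before
#' clustering so the merge tree does not depend on input column order.
#'
#' @param matrix numeric matrix, genes (or features) x samples.
#' @return list with `sample_order` (leaf order, left to right), `merge`,
#'   `height`, `labels` (the `hclust` fields) and `hclust`, the full
#'   object.
#' @export
cluster_samples <- function(matrix, method = "complete") {
  stopifnot(ncol(matrix) >= 2L)
  m <- matrix[, order(colnames(matrix)), drop = FALSE]
  hc <- stats::hclust(stats::dist(t(m), method = "euclidean"), method = method)
  list(sample_order = hc$labels[hc$order], merge = hc$merge,
       height = hc$height, labels = hc$labels, hclust = hc)
}

#' Literature-driven gene network on an interactome scaffold
#'
#' Nodes are the literature-associated genes with their association
#' scores; edges are the interactome pairs whose both endpoints are
#' scored (the induced subgraph), carrying the interactome confidence
#' score. Each retained edge is annotated with its co-citation count:
#' the number of corpus publications whose annotated gene set contains
#' both endpoints. Self-edges are dropped; edges are undirected and
#' stored with lexicographically ordered endpoints.
#'
#' @param gene_scores named numeric vector, gene -> association score.
#' @param interactome data.frame with columns gene_a, gene_b, score.
#' @param corpus a `corpus` (restricts co-citation to its pmids); may be
#'   `NULL` to use every annotation entry.
#' @param gene_annotations named list, pmid -> character vector of genes.
#' @return object of class `gene_network`: `nodes` (data.frame gene,
#'   score) and `edges` (data.frame gene_a, gene_b, score, cocitation).
#' @export
build_gene_network <- function(gene_scores, interactome, corpus = NULL,
                               gene_annotations = list()) {
  if (length(gene_scores) == 0L) stop("no scored genes")
  genes <- names(gene_scores)
  nodes <- data.frame(gene = genes, score = as.numeric(gene_scores),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$gene), , drop = FALSE]
  rownames(nodes) <- NULL

  if (!is.null(corpus))
    gene_annotations <- gene_annotations[
      names(gene_annotations) %in% corpus_pmids(corpus)]

  if (nrow(interactome) > 0L) {
    a <- pmin(as.character(interactome$gene_a), as.character(interactome$gene_b))
    b <- pmax(as.character(interactome$gene_a), as.character(interactome$gene_b))
    keep <- a %in% genes & b %in% genes & a != b
    ed <- data.frame(gene_a = a[keep], gene_b = b[keep],
                     score = as.numeric(interactome$score)[keep],
                     stringsAsFactors = FALSE)
    ed <- ed[!duplicated(paste(ed$gene_a, ed$gene_b, sep = "\r")), , drop = FALSE]
    ed <- ed[order(ed$gene_a, ed$gene_b), , drop = FALSE]
  } else {
    ed <- data.frame(gene_a = character(), gene_b = character(),
                     score = numeric(), stringsAsFactors = FALSE)
  }
  ed$cocitation <- if (nrow(ed) == 0L) integer() else
    vapply(seq_len(nrow(ed)), function(i)
      sum(vapply(gene_annotations, function(gs)
        ed$gene_a[[i]] %in% gs && ed$gene_b[[i]] %in% gs, TRUE)),
      0L)
  rownames(ed) <- NULL
  structure(list(nodes = nodes, edges = ed), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("gene network: ", nrow(x$nodes), " node(s), ", nrow(x$edges),
      " edge(s)\n", sep = "")
  invisible(x)
}

#' Export a gene network as GraphML
#' @export
write_network_graphml <- function(network, path) {
  g <- igraph::graph_from_data_frame(
    if (nrow(network$edges)) network$edges else
      data.frame(gene_a = character(), gene_b = character()),
    directed = FALSE, vertices = network$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a generic numeric matrix as TSV (row names in first column)
#' @export
write_matrix_tsv <- function(matrix, path, id_col = "id") {
  df <- data.frame(rownames(matrix), matrix, stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(df) <- c(id_col, colnames(matrix))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
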