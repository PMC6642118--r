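# End-to-end orchestration: corpus build -> MeSH prioritisation -> gene
# network -> expression ingestion -> downstream analyses, with a
# machine-readable run manifest. All stages run offline against files;
# live retrieval adapters can be slotted in via the fetcher contract.

#' Run configuration
#'
#' Exactly one of `query` / `pmid_file` must be set. In query mode the
#' record stream is consumed in its given order (the retrieval source's
#' relevance order); in pmid-list mode records are looked up by PMID in
#' the stream and kept in list order.
#'
#' @param records path to the publication records (JSON-lines or
#'   MEDLINE XML; dialect inferred from the extension).
#' @param mesh,background paths to the vocabulary TSV and the global
#'   term-frequency TSV (columns ui, count, with header).
#' @param interactome path to the scored interactome edge list TSV.
#' @param gene_annotations path to the pmid -> genes TSV (semicolon
#'   joined); `gene_scores` to the gene association-score TSV.
#' @param series_matrix,platform paths to the expression series and its
#'   probe->gene dictionary (optional when `skip_expression`).
#' @param compare_terms optional path to a term list (one per line) to
#'   compare against the prioritised terms with all similarity measures.
#' @param email recorded in the manifest (courtesy header for any live
#'   retrieval adapter; unused offline).
#' @param max_records optional cap on the corpus size, in retrieval order.
#' @param skip_expression bypass expression retrieval and the analyses
#'   that need it.
#' @param seed integer recorded in the manifest and used for any
#'   randomised step.
#' @param top_variable number of most-variable genes for the z-score
#'   matrix.
#' @param out_dir output directory for all stage outputs.
#' @export
run_config <- function(out_dir,
                       records, mesh, background, interactome = NULL,
                       gene_annotations = NULL, gene_scores = NULL,
                       series_matrix = NULL, platform = NULL,
                       compare_terms = NULL,
                       query = NULL, pmid_file = NULL,
                       email = "user@example.org",
                       max_records = NULL, skip_expression = FALSE,
                       seed = 1L, top_variable = 20L) {
  if (is.null(query) == is.null(pmid_file))
    stop("exactly one of query / pmid_file must be set")
  structure(list(out_dir = out_dir, records = records, mesh = mesh,
                 background = background, interactome = interactome,
                 gene_annotations = gene_annotations,
                 gene_scores = gene_scores,
                 series_matrix = series_matrix, platform = platform,
                 compare_terms = compare_terms,
                 query = query, pmid_file = pmid_file, email = email,
                 max_records = max_records,
                 skip_expression = isTRUE(skip_expression),
                 seed = as.integer(seed),
                 top_variable = as.integer(top_variable)),
            class = "run_config")
}

.read_background <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}

.read_interactome <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("gene_a", "gene_b", "score")
  df
}

.read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  ann <- lapply(strsplit(df[[2L]], ";", fixed = TRUE), function(g) g[nzchar(g)])
  names(ann) <- df[[1L]]
  ann
}

.read_gene_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}

#' Execute the full pipeline
#'
#' Stages, in order: corpus build, MeSH prioritisation, gene network,
#' expression ingestion (probe collapse + sample stratification; skipped
#' with `skip_expression`), downstream analyses (PCA, most-variable-gene
#' z-scores with sample clustering), and an optional term-set similarity
#' report. Each stage's outputs are written under `out_dir` and listed
#' in `manifest.json`; a stage failure aborts with the stage name and
#' leaves partial outputs plus a failure marker in the manifest.
#'
#' @param config a [run_config()].
#' @return (invisibly) the manifest as a list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  manifest <- list(seed = config$seed, email = config$email,
                   query = config$query %||% "",
                   mode = if (is.null(config$query)) "pmid-list" else "query",
                   files = character(), warnings = character(),
                   analyses = list(), failed_stage = NULL)
  warn <- function(w) {
    manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  emit <- function(name) manifest$files <<- c(manifest$files, name)
  stage <- function(name, expr) {
    res <- tryCatch(withCallingHandlers(expr, warning = warn),
                    error = function(e) e)
    if (inherits(res, "error")) {
      manifest$failed_stage <<- name
      .write_manifest(manifest, out("manifest.json"))
      stop("stage '", name, "' failed: ", conditionMessage(res))
    }
    res
  }
  set.seed(config$seed)

  corpus <- stage("corpus", {
    dialect <- if (grepl("\\.xml$", config$records)) "medline-xml" else "json"
    src <- parse_records(config$records, dialect,
                         query = config$query %||% "")
    cp <- if (!is.null(config$pmid_file)) {
      pmids <- readLines(config$pmid_file, warn = FALSE)
      build_corpus_from_pmids(pmids[nzchar(pmids)], fixture_fetcher(src))
    } else src
    if (!is.null(config$max_records)) cp <- limit_corpus(cp, config$max_records)
    write_corpus(cp, out("corpus.tsv"), "tsv"); emit("corpus.tsv")
    write_corpus(cp, out("corpus.jsonl"), "json"); emit("corpus.jsonl")
    cp
  })

  prio <- stage("prioritisation", {
    tree <- parse_mesh(config$mesh, "tsv")
    bg <- .read_background(config$background)
    pr <- prioritise(corpus, tree, bg)
    write_priority(pr, out("prioritised_terms.tsv")); emit("prioritised_terms.tsv")
    list(priority = pr, tree = tree, background = bg)
  })

  if (!is.null(config$interactome) && !is.null(config$gene_scores)) {
    stage("network", {
      net <- build_gene_network(
        .read_gene_scores(config$gene_scores),
        .read_interactome(config$interactome),
        corpus,
        if (!is.null(config$gene_annotations))
          .read_annotations(config$gene_annotations) else list())
      utils::write.table(net$nodes, out("network_nodes.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE); emit("network_nodes.tsv")
      utils::write.table(net$edges, out("network_edges.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE); emit("network_edges.tsv")
      write_network_graphml(net, out("network.graphml")); emit("network.graphml")
      net
    })
  }

  tuples <- character()
  if (!config$skip_expression && !is.null(config$series_matrix)) {
    series <- stage("expression", {
      s <- parse_series_matrix(config$series_matrix, config$platform)
      utils::write.table(data.frame(sample = rownames(s$pdata), s$pdata,
                                    check.names = FALSE),
                         out("pdata.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE); emit("pdata.tsv")
      s
    })
    gene_mat <- stage("collapse", {
      gm <- collapse_probes(series$edata, series$tdata)
      write_matrix_tsv(gm, out("gene_matrix.tsv"), "gene"); emit("gene_matrix.tsv")
      gm
    })
    stage("stratify", {
      grp <- stratify_samples(series$pdata)
      utils::write.table(data.frame(sample = rownames(grp), grp),
                         out("groups.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE); emit("groups.tsv")
      grp
    })
    stage("analyses", {
      pca <- expr_pca(gene_mat, k = min(3L, min(dim(gene_mat))))
      write_matrix_tsv(round(pca$scores, 9), out("pca_scores.tsv"), "sample")
      emit("pca_scores.tsv")
      utils::write.table(data.frame(component = seq_along(pca$explained_ratio_all),
                                    explained_ratio = round(pca$explained_ratio_all, 9)),
                         out("pca_explained.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE); emit("pca_explained.tsv")
      top <- top_variable_genes(gene_mat, config$top_variable)
      z <- zscore_rows(gene_mat[top, , drop = FALSE])
      write_matrix_tsv(round(z, 9), out("zscore_matrix.tsv"), "gene")
      emit("zscore_matrix.tsv")
      cl <- cluster_samples(z)
      jsonlite::write_json(list(sample_order = cl$sample_order,
                                merge = cl$merge,
                                height = round(cl$height, 9),
                                labels = cl$labels),
                           out("cluster.json"), digits = NA)
      emit("cluster.json")
      NULL
    })
    analyses_done <- c("probe_collapse", "stratification", "pca",
                       "top_variable_zscores", "sample_clustering")
    for (r in corpus$records)
      for (g in r$gse_codes)
        if (identical(g, series$accession))
          tuples[[paste0(r$pmid, ":", g)]] <- paste(analyses_done, collapse = ";")
    manifest$analyses <- as.list(tuples)
  }

  if (!is.null(config$compare_terms)) {
    stage("similarity", {
      terms_b <- readLines(config$compare_terms, warn = FALSE)
      terms_b <- terms_b[nzchar(terms_b)]
      top_a <- utils::head(prio$priority$ui, 10L)
      cfg <- similarity_config(
        ic_table = ic_cumulative(prio$tree, prio$background))
      rows <- lapply(.sim_measures, function(m) {
        s <- set_similarity(prio$tree, top_a, terms_b, m, cfg)
        data.frame(measure = m, score = round(s, 6),
                   significant = significance_flag(s))
      })
      utils::write.table(do.call(rbind, rows), out("similarity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit("similarity.tsv")
      NULL
    })
  }

  manifest <- .write_manifest(manifest, out("manifest.json"))
  invisible(manifest)
}

.write_manifest <- function(manifest, path) {
  manifest$files <- sort(unique(c(manifest$files, basename(path))))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(manifest)
}
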