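# Seeded generator of a consistent offline input bundle: a synthetic
# vocabulary tree, literature records annotated from it (with a planted
# "deep, topic-enriched, globally rare" term set), a global background
# frequency table, a two-group expression series with a planted mean
# shift, a probe->gene platform dictionary, and a scored interactome
# over the record-annotated genes.

.fixture_defaults <- function() {
  list(
    n_descriptors = 60L,    # vocabulary size (incl. planted terms)
    max_depth = 5L,         # depth of the synthetic forest
    n_categories = 3L,
    n_planted = 5L,         # planted topic terms, placed at max_depth
    planted_prevalence = 0.8,  # fraction of records carrying each planted term
    fillers_per_record = 3L,
    n_records = 30L,
    n_genes = 40L,
    probes_per_gene = 3L,
    n_samples = 100L,       # half cancer, half normal
    n_shift_genes = 10L,
    shift_sd = 2.0,         # planted group shift, in noise-sd units
    noise_sd = 1.0,
    n_interactome_edges = 60L,
    genes_per_record = c(3L, 8L),
    gse = "GSE90001", gpl = "GPL5000")
}

#' Generate the synthetic fixture bundle
#'
#' Emits, under `out_dir`: `mesh.tsv` (vocabulary), `records.jsonl`
#' (literature records), `pmids.txt`, `background.tsv` (global term
#' frequencies), `series_matrix.txt` (expression), `platform.tsv`
#' (probe->gene), `interactome.tsv`, `gene_annotations.tsv`
#' (pmid -> genes) and `gene_scores.tsv` (association scores). The same
#' seed and sizes always reproduce the same bundle byte for byte.
#'
#' The planted term set is deep (max depth), carried by most records,
#' and globally rare in the background -- so it should dominate all
#' three prioritisation criteria. The expression series holds two
#' sample groups with a configurable mean shift on a gene subset over
#' Gaussian noise.
#'
#' @param seed integer RNG seed.
#' @param sizes named list overriding the defaults (see source).
#' @param out_dir output directory, created if needed; `NULL` keeps the
#'   bundle in memory only.
#' @return (invisibly) list with the in-memory objects, the planted
#'   term UIs, the shifted gene names, and the file paths written.
#' @export
generate_fixtures <- function(seed, sizes = list(), out_dir = NULL) {
  p <- utils::modifyList(.fixture_defaults(), sizes)
  if (p$max_depth > p$n_descriptors)
    stop("infeasible sizes: max_depth exceeds n_descriptors")
  if (p$n_planted + p$n_categories + p$max_depth > p$n_descriptors)
    stop("infeasible sizes: not enough descriptors for categories, spine and planted terms")
  if (p$n_shift_genes > p$n_genes)
    stop("infeasible sizes: n_shift_genes exceeds n_genes")
  set.seed(as.integer(seed))

  voc <- .gen_tree(p)
  lit <- .gen_literature(p, voc)
  expr <- .gen_expression(p)
  net <- .gen_network(p, lit)

  paths <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f <- function(name) file.path(out_dir, name)
    utils::write.table(voc$tsv, f("mesh.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    writeLines(lit$jsonl, f("records.jsonl"))
    writeLines(lit$pmids, f("pmids.txt"))
    utils::write.table(data.frame(ui = names(voc$background),
                                  count = as.numeric(voc$background)),
                       f("background.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_series_matrix(expr$series, f("series_matrix.txt"))
    utils::write.table(expr$platform, f("platform.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(net$interactome, f("interactome.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(pmid = names(net$annotations),
                                  genes = vapply(net$annotations, paste,
                                                 "", collapse = ";")),
                       f("gene_annotations.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(data.frame(gene = names(net$gene_scores),
                                  score = as.numeric(net$gene_scores)),
                       f("gene_scores.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- file.path(out_dir,
                       c("mesh.tsv", "records.jsonl", "pmids.txt",
                         "background.tsv", "series_matrix.txt",
                         "platform.tsv", "interactome.tsv",
                         "gene_annotations.tsv", "gene_scores.tsv"))
  }
  invisible(list(tree = voc$tree, planted = voc$planted,
                 background = voc$background,
                 corpus = lit$corpus, series = expr$series,
                 platform = expr$platform, shifted_genes = expr$shifted,
                 interactome = net$interactome,
                 annotations = net$annotations,
                 gene_scores = net$gene_scores,
                 sizes = p, paths = paths))
}

.gen_tree <- function(p) {
  cats <- paste0(LETTERS[seq_len(p$n_categories)],
                 sprintf("%02d", seq_len(p$n_categories)))
  ui <- sprintf("D%06d", seq_len(p$n_descriptors))
  name <- sprintf("term-%03d", seq_len(p$n_descriptors))
  placements <- vector("list", p$n_descriptors)
  # category roots first
  for (i in seq_len(p$n_categories)) placements[[i]] <- cats[[i]]
  positions <- cats
  kid_counter <- new.env(parent = emptyenv())
  new_child <- function(parent) {
    k <- (get0(parent, envir = kid_counter) %||% 0L) + 1L
    assign(parent, k, envir = kid_counter)
    paste0(parent, ".", sprintf("%03d", 100L + k))
  }
  # a spine down to max_depth so deep placements exist
  spine_n <- p$max_depth - 1L
  cur <- cats[[1L]]
  for (i in seq_len(spine_n)) {
    cur <- new_child(cur)
    placements[[p$n_categories + i]] <- cur
    positions <- c(positions, cur)
  }
  # planted terms: children of deepest spine nodes (depth = max_depth)
  deep_parents <- positions[vapply(positions, .code_depth, 0L) == p$max_depth - 1L]
  planted_idx <- seq.int(p$n_categories + spine_n + 1L,
                         length.out = p$n_planted)
  for (i in planted_idx) {
    pp <- new_child(sample(deep_parents, 1L))
    placements[[i]] <- pp
    positions <- c(positions, pp)
  }
  # fillers: attach below random positions of depth < max_depth - 1, so
  # every filler sits strictly above the planted depth
  filler_idx <- if (max(planted_idx) < p$n_descriptors)
    seq.int(max(planted_idx) + 1L, p$n_descriptors) else integer()
  for (i in filler_idx) {
    ok <- positions[vapply(positions, .code_depth, 0L) < p$max_depth - 1L]
    pp <- new_child(sample(ok, 1L))
    placements[[i]] <- pp
    positions <- c(positions, pp)
    # occasional second placement: multi-placement descriptors
    if (stats::runif(1) < 0.15) {
      pp2 <- new_child(sample(ok, 1L))
      placements[[i]] <- c(placements[[i]], pp2)
      positions <- c(positions, pp2)
    }
  }
  tsv <- data.frame(ui = ui, name = name,
                    tn = vapply(placements, paste, "", collapse = ";"),
                    stringsAsFactors = FALSE)
  tf <- tempfile(fileext = ".tsv")
  utils::write.table(tsv, tf, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  tree <- parse_mesh(tf, "tsv")
  unlink(tf)
  planted <- ui[planted_idx]
  filler <- setdiff(ui, planted)
  background <- stats::setNames(numeric(p$n_descriptors), ui)
  background[planted] <- round(stats::runif(p$n_planted, 10, 100))
  background[filler] <- round(stats::runif(length(filler), 1e4, 1e6))
  list(tree = tree, tsv = tsv, planted = planted, background = background)
}

.gen_literature <- function(p, voc) {
  ui <- names(voc$tree$descriptors)
  filler <- setdiff(ui, voc$planted)
  # fillers usable as headings: skip the category roots themselves
  filler_pool <- filler[vapply(filler, function(u)
    descriptor_depth(voc$tree, u, "max") >= 2L, TRUE)]
  records <- lapply(seq_len(p$n_records), function(i) {
    carried <- voc$planted[stats::runif(p$n_planted) < p$planted_prevalence]
    if (length(carried) == 0L) carried <- voc$planted[[1L]]
    heads <- c(carried,
               sample(filler_pool, min(p$fillers_per_record, length(filler_pool))))
    with_gse <- i <= 3L  # first records carry the expression series link
    list(pmid = as.character(100000L + i),
         title = sprintf("Synthetic breast cancer study %d", i),
         authors = c(sprintf("Author%s A", LETTERS[(i %% 26L) + 1L]), "Coauthor B"),
         journal = "Journal of Synthetic Data",
         pub_date = sprintf("2018-%02d-%02d", (i %% 12L) + 1L, (i %% 27L) + 1L),
         mesh_headings = heads,
         gse_codes = if (with_gse) p$gse else character(),
         platforms = if (with_gse) p$gpl else character(),
         ftp_links = if (with_gse)
           paste0("ftp://ftp.example.org/geo/", p$gse) else character(),
         analyses = character())
  })
  corpus <- .new_corpus(lapply(records, .new_record),
                        query = "synthetic topic", source_tag = "fixture")
  jsonl <- vapply(corpus$records, function(r)
    as.character(jsonlite::toJSON(r, auto_unbox = FALSE)), "")
  list(corpus = corpus, jsonl = jsonl, pmids = corpus_pmids(corpus))
}

.gen_expression <- function(p) {
  genes <- sprintf("GENE%03d", seq_len(p$n_genes))
  probes <- sprintf("P%04d", seq_len(p$n_genes * p$probes_per_gene))
  probe_gene <- rep(genes, each = p$probes_per_gene)
  n_half <- p$n_samples %/% 2L
  samples <- sprintf("GSM%05d", 9000L + seq_len(p$n_samples))
  group <- rep(c("cancer", "normal"), c(n_half, p$n_samples - n_half))
  title <- ifelse(group == "cancer",
                  sprintf("breast tumor tissue, sample %d", seq_len(p$n_samples)),
                  sprintf("adjacent normal tissue, sample %d", seq_len(p$n_samples)))
  shifted <- genes[seq_len(p$n_shift_genes)]
  base <- stats::rnorm(p$n_genes, 8, 1.5)           # per-gene baseline
  gene_expr <- matrix(base, p$n_genes, p$n_samples) +
    matrix(stats::rnorm(p$n_genes * p$n_samples, 0, p$noise_sd),
           p$n_genes, p$n_samples)
  gene_expr[seq_len(p$n_shift_genes), group == "cancer"] <-
    gene_expr[seq_len(p$n_shift_genes), group == "cancer"] +
    p$shift_sd * p$noise_sd
  # probe level: gene value + small probe offset
  edata <- gene_expr[match(probe_gene, genes), , drop = FALSE] +
    matrix(stats::rnorm(length(probes) * p$n_samples, 0, 0.1),
           length(probes), p$n_samples)
  edata <- round(edata, 6)
  dimnames(edata) <- list(probes, samples)
  pdata <- data.frame(title = title,
                      geo_accession = samples,
                      characteristics_ch1 = "tissue: breast",
                      stringsAsFactors = FALSE, row.names = samples)
  platform <- data.frame(probe = probes, gene = probe_gene,
                         platform = p$gpl, stringsAsFactors = FALSE)
  series <- .new_geo_series(p$gse, pdata, edata, platform)
  list(series = series, platform = platform, shifted = shifted)
}

.gen_network <- function(p, lit) {
  genes <- sprintf("GENE%03d", seq_len(p$n_genes))
  annotations <- lapply(lit$corpus$records, function(r)
    sort(sample(genes, min(length(genes),
                           sample(seq(p$genes_per_record[[1L]],
                                      p$genes_per_record[[2L]]), 1L)))))
  names(annotations) <- corpus_pmids(lit$corpus)
  counts <- table(unlist(annotations, use.names = FALSE))
  gene_scores <- stats::setNames(as.numeric(counts), names(counts))
  pool <- c(names(gene_scores), sprintf("EXT%02d", 1:5))  # some off-corpus genes
  pairs <- t(utils::combn(pool, 2L))
  take <- sample(nrow(pairs), min(p$n_interactome_edges, nrow(pairs)))
  interactome <- data.frame(gene_a = pairs[take, 1L],
                            gene_b = pairs[take, 2L],
                            score = round(stats::runif(length(take), 0.1, 1), 4),
                            stringsAsFactors = FALSE)
  list(interactome = interactome, annotations = annotations,
       gene_scores = gene_scores)
}
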