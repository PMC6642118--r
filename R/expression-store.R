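# One expression series is represented as three data packages:
#   pdata -- sample-level phenotype/experimental metadata (free text),
#   edata -- the probe x sample numeric expression matrix,
#   tdata -- the platform dictionary mapping probes to gene symbols.

.new_geo_series <- function(accession, pdata, edata, tdata = NULL) {
  stopifnot(is.matrix(edata), is.numeric(edata))
  if (!all(colnames(edata) %in% rownames(pdata)))
    stop("every expression column must have a pdata row")
  if (anyDuplicated(rownames(edata))) stop("duplicate probe ids in edata")
  if (!is.null(tdata) && anyDuplicated(tdata$probe))
    stop("duplicate probe ids in tdata")
  structure(list(accession = accession, pdata = pdata, edata = edata,
                 tdata = tdata),
            class = "geo_series")
}

#' @export
print.geo_series <- function(x, ...) {
  cat("series ", x$accession, ": ", nrow(x$edata), " probes x ",
      ncol(x$edata), " samples, ", ncol(x$pdata),
      " phenotype field(s)\n", sep = "")
  invisible(x)
}

#' Parse a GEO-style series-matrix file
#'
#' Expects bang-prefixed metadata lines (`!Series_...`, `!Sample_...`)
#' followed by the expression table between `!series_matrix_table_begin`
#' and `!series_matrix_table_end`. Repeated `!Sample_*` keys (e.g.
#' several `characteristics_ch1` lines) become numbered pdata columns.
#' Non-numeric expression cells (including `null` / `NA` / empty) are
#' recorded as missing values with a warning. Plain and gzip-compressed
#' files are both accepted.
#'
#' @param source path to the series-matrix file.
#' @param platform optional path to a platform annotation TSV
#'   (columns probe, gene, optionally platform) used as tdata.
#' @return a `geo_series`.
#' @export
parse_series_matrix <- function(source, platform = NULL) {
  con <- gzfile(source, "rt"); on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  tb <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  te <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(tb) != 1L || length(te) != 1L || te <= tb + 1L)
    stop("series matrix lacks a table_begin/table_end block")

  split_row <- function(ln) .unquote(strsplit(ln, "\t", fixed = TRUE)[[1L]])
  meta <- lines[seq_len(tb - 1L)]
  meta <- meta[startsWith(meta, "!")]
  acc <- ""
  sample_meta <- list()
  for (ln in meta) {
    f <- split_row(ln)
    key <- sub("^!", "", f[[1L]])
    if (identical(key, "Series_geo_accession") && length(f) > 1L) acc <- f[[2L]]
    if (startsWith(key, "Sample_")) {
      k0 <- sub("^Sample_", "", key)
      k <- k0; i <- 1L
      while (k %in% names(sample_meta)) { i <- i + 1L; k <- paste0(k0, ".", i) }
      sample_meta[[k]] <- f[-1L]
    }
  }

  header <- split_row(lines[[tb + 1L]])
  samples <- header[-1L]
  body <- lines[seq.int(tb + 2L, te - 1L)]
  rows <- lapply(body, split_row)
  probes <- vapply(rows, `[[`, "", 1L)
  vals <- t(vapply(rows, function(r) {
    v <- suppressWarnings(as.numeric(r[-1L]))
    length(v) <- length(samples)
    v
  }, numeric(length(samples))))
  if (length(samples) == 1L) vals <- matrix(vals, ncol = 1L)
  dimnames(vals) <- list(probes, samples)
  n_missing <- sum(is.na(vals))
  if (n_missing > 0L)
    warning(n_missing, " expression cell(s) recorded as missing")

  if (length(sample_meta) == 0L)
    sample_meta <- list(geo_accession = samples)
  pdata <- as.data.frame(lapply(sample_meta, function(v) {
    length(v) <- length(samples); ifelse(is.na(v), "", v)
  }), stringsAsFactors = FALSE, check.names = FALSE)
  rownames(pdata) <- if ("geo_accession" %in% names(sample_meta))
    sample_meta$geo_accession else samples

  tdata <- if (!is.null(platform)) read_platform_table(platform) else NULL
  .new_geo_series(acc, pdata, vals, tdata)
}

#' Read a platform annotation table (probe -> gene symbol)
#'
#' TSV with a header line; the first column is the probe id, a column
#' named `gene` (or the second column) the gene symbol, and an optional
#' `platform` column.
#' @export
read_platform_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  probe_col <- 1L
  gene_col <- if ("gene" %in% names(df)) "gene" else 2L
  out <- data.frame(probe = as.character(df[[probe_col]]),
                    gene = as.character(df[[gene_col]]),
                    stringsAsFactors = FALSE)
  if ("platform" %in% names(df)) out$platform <- as.character(df$platform)
  out
}

#' Write a series back to the series-matrix dialect (round-trip capable)
#' @export
write_series_matrix <- function(series, path) {
  q <- function(x) paste0('"', x, '"')
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(paste0("!Series_geo_accession\t", q(series$accession)), con)
  samples <- rownames(series$pdata)
  for (k in names(series$pdata))
    writeLines(paste(c(paste0("!Sample_", k), q(series$pdata[[k]])),
                     collapse = "\t"), con)
  if (!"geo_accession" %in% names(series$pdata))
    writeLines(paste(c("!Sample_geo_accession", q(samples)), collapse = "\t"), con)
  writeLines("!series_matrix_table_begin", con)
  writeLines(paste(c(q("ID_REF"), q(colnames(series$edata))), collapse = "\t"), con)
  for (i in seq_len(nrow(series$edata))) {
    v <- series$edata[i, ]
    writeLines(paste(c(q(rownames(series$edata)[i]),
                       ifelse(is.na(v), "null", format(v, digits = 15, trim = TRUE,
                                                       scientific = FALSE))),
                     collapse = "\t"), con)
  }
  writeLines("!series_matrix_table_end", con)
  invisible(path)
}

#' Collapse probe-level expression to gene level
#'
#' Probes mapping to the same gene symbol are merged by the chosen
#' statistic (arithmetic mean by default), excluding missing values
#' cell-wise; probes with no gene mapping are dropped and counted in the
#' `dropped_probes` attribute.
#'
#' @param edata numeric matrix, probes x samples.
#' @param tdata data.frame with columns probe, gene.
#' @param statistic `"mean"` (default), `"median"`, or `"max_variance"`
#'   (the single most variable probe represents the gene).
#' @return numeric matrix, genes x samples.
#' @export
collapse_probes <- function(edata, tdata, statistic = c("mean", "median", "max_variance")) {
  statistic <- match.arg(statistic)
  map <- stats::setNames(tdata$gene, tdata$probe)
  genes <- unname(map[rownames(edata)])
  mapped <- !is.na(genes) & nzchar(genes)
  if (!any(mapped)) stop("no probe maps to a gene")
  dropped <- sum(!mapped)
  e <- edata[mapped, , drop = FALSE]
  g <- genes[mapped]
  out_genes <- sort(unique(g))
  out <- switch(statistic,
    mean = {
      num <- rowsum(ifelse(is.na(e), 0, e), g)
      den <- rowsum((!is.na(e)) * 1, g)
      res <- num / den
      res[den == 0] <- NA_real_
      res[out_genes, , drop = FALSE]
    },
    median = t(vapply(out_genes, function(gg)
      apply(e[g == gg, , drop = FALSE], 2L, stats::median, na.rm = TRUE),
      numeric(ncol(e)))),
    max_variance = t(vapply(out_genes, function(gg) {
      sub <- e[g == gg, , drop = FALSE]
      v <- apply(sub, 1L, stats::var, na.rm = TRUE)
      sub[which.max(ifelse(is.na(v), -Inf, v)), ]
    }, numeric(ncol(e)))))
  if (ncol(e) == 1L) out <- matrix(out, ncol = 1L)
  dimnames(out) <- list(out_genes, colnames(edata))
  attr(out, "dropped_probes") <- dropped
  out
}

#' Default keyword lexicon for sample stratification
#'
#' Two groups: cancer-family keywords and normal/control keywords.
#' @export
default_lexicon <- function() {
  lex <- list(
    cancer = c("tumor", "tumour", "cancer", "carcinoma", "malignant", "metasta"),
    normal = c("normal", "control", "healthy", "benign", "adjacent"))
  attr(lex, "cancer_groups") <- "cancer"
  attr(lex, "normal_groups") <- "normal"
  lex
}

#' Stratify samples into biological groups by keyword mining
#'
#' All phenotype values of a sample are concatenated and matched
#' case-insensitively against each group's keywords; the group with the
#' most keyword occurrences wins. Ties and zero hits give `"unknown"`.
#' The cancer flag reports whether the winning group belongs to the
#' cancer or the normal family of the lexicon.
#'
#' @param pdata data.frame of phenotype values, rownames = samples.
#' @param lexicon named list group -> keyword vector (see
#'   [default_lexicon()]).
#' @return data.frame with columns `group` and `cancer_flag`, one row
#'   per sample.
#' @export
stratify_samples <- function(pdata, lexicon = default_lexicon()) {
  if (length(lexicon) == 0L) stop("lexicon is empty")
  cancer_groups <- attr(lexicon, "cancer_groups") %||% "cancer"
  normal_groups <- attr(lexicon, "normal_groups") %||% "normal"
  samples <- rownames(pdata)
  blob <- tolower(apply(pdata, 1L, paste, collapse = " "))
  hits <- vapply(lexicon, function(kws)
    vapply(blob, function(s)
      sum(vapply(kws, function(k) {
        m <- gregexpr(k, s, fixed = TRUE)[[1L]]
        if (m[[1L]] == -1L) 0L else length(m)
      }, 0L)), 0L),
    integer(length(samples)))
  if (length(samples) == 1L) hits <- matrix(hits, nrow = 1L,
                                            dimnames = list(samples, names(lexicon)))
  group <- apply(hits, 1L, function(h) {
    if (max(h) == 0L || sum(h == max(h)) > 1L) "unknown"
    else names(lexicon)[which.max(h)]
  })
  flag <- ifelse(group %in% cancer_groups, "cancer",
                 ifelse(group %in% normal_groups, "normal", "unknown"))
  data.frame(group = unname(group), cancer_flag = unname(flag),
             row.names = samples, stringsAsFactors = FALSE)
}
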