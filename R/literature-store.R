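# Publication records carry the per-paper metadata block: PMID, title,
# authors, journal, ISO date, MeSH headings, linked GEO series (GSE),
# platforms (GPL), ftp links and downstream analysis labels.

.record_fields <- c("pmid", "title", "authors", "journal", "pub_date",
                    "mesh_headings", "gse_codes", "platforms", "ftp_links",
                    "analyses")
.list_fields <- c("authors", "mesh_headings", "gse_codes", "platforms",
                  "ftp_links", "analyses")

.new_record <- function(fields) {
  r <- stats::setNames(vector("list", length(.record_fields)), .record_fields)
  for (f in .record_fields)
    r[[f]] <- if (f %in% .list_fields) character() else ""
  for (f in intersect(names(fields), .record_fields)) {
    v <- fields[[f]]
    r[[f]] <- if (f %in% .list_fields) as.character(v %||% character())
              else as.character(v %||% "")[1L]
  }
  .validate_record(r)
  r
}

.validate_record <- function(r) {
  if (!nzchar(r$pmid)) stop("record without pmid")
  if (nzchar(r$pub_date) &&
      (!grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", r$pub_date) ||
       is.na(as.Date(r$pub_date, "%Y-%m-%d"))))
    stop("pub_date must be yyyy-mm-dd, got '", r$pub_date, "'")
  bad_gse <- r$gse_codes[!grepl("^GSE[0-9]+$", r$gse_codes)]
  if (length(bad_gse)) stop("invalid GSE accession: ", bad_gse[[1L]])
  bad_gpl <- r$platforms[!grepl("^GPL[0-9]+$", r$platforms)]
  if (length(bad_gpl)) stop("invalid platform accession: ", bad_gpl[[1L]])
  invisible(r)
}

.new_corpus <- function(records, query = "", source_tag = "") {
  pmids <- vapply(records, `[[`, "", "pmid")
  drop <- duplicated(pmids)
  if (any(drop)) {
    warning("dropping duplicated pmid(s): ",
            paste(unique(pmids[drop]), collapse = ", "))
    records <- records[!drop]
  }
  structure(list(records = records, query = query, source_tag = source_tag),
            class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat("corpus of ", length(x$records), " record(s)",
      if (nzchar(x$query)) paste0(" [query: ", x$query, "]"), "\n", sep = "")
  invisible(x)
}

#' @export
length.corpus <- function(x) length(x$records)

corpus_pmids <- function(corpus) vapply(corpus$records, `[[`, "", "pmid")

#' Parse publication records into a corpus
#'
#' Retrieval order is preserved: the corpus order is the input order, as
#' ranked by whatever retrieval source produced the stream. Records
#' without a PMID are rejected with a warning; a second occurrence of a
#' PMID is dropped with a warning.
#'
#' @param source path to the record stream.
#' @param dialect `"json"` (JSON-lines, one record object per line with
#'   the metadata field names) or `"medline-xml"` (PubmedArticleSet).
#' @param query,source_tag provenance labels stored on the corpus.
#' @return a `corpus`.
#' @export
parse_records <- function(source, dialect = c("json", "medline-xml"),
                          query = "", source_tag = dialect) {
  dialect <- match.arg(dialect)
  raw <- if (dialect == "json") .records_from_jsonl(source)
         else .records_from_medline(source)
  records <- list()
  for (f in raw) {
    r <- tryCatch(.new_record(f), error = function(e) {
      warning("record rejected: ", conditionMessage(e)); NULL
    })
    if (!is.null(r)) records[[length(records) + 1L]] <- r
  }
  .new_corpus(records, query = query, source_tag = source_tag[[1L]])
}

.records_from_jsonl <- function(source) {
  lines <- readLines(source, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) jsonlite::fromJSON(ln, simplifyVector = TRUE))
}

.records_from_medline <- function(source) {
  doc <- xml2::read_xml(source)
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  lapply(arts, function(a) {
    txt <- function(xp) {
      n <- xml2::xml_find_first(a, xp)
      if (inherits(n, "xml_missing")) "" else xml2::xml_text(n)
    }
    all_txt <- function(xp) xml2::xml_text(xml2::xml_find_all(a, xp))
    authors <- vapply(xml2::xml_find_all(a, ".//AuthorList/Author"),
                      function(au) {
      ln <- xml2::xml_find_first(au, "./LastName")
      ini <- xml2::xml_find_first(au, "./Initials")
      trimws(paste(if (!inherits(ln, "xml_missing")) xml2::xml_text(ln) else "",
                   if (!inherits(ini, "xml_missing")) xml2::xml_text(ini) else ""))
    }, "")
    y <- txt(".//Article/Journal/JournalIssue/PubDate/Year")
    m <- txt(".//Article/Journal/JournalIssue/PubDate/Month")
    d <- txt(".//Article/Journal/JournalIssue/PubDate/Day")
    dd <- suppressWarnings(as.integer(d))
    if (is.na(dd) || dd < 1L) dd <- 1L
    pub_date <- if (nzchar(y)) sprintf("%s-%02d-%02d", y, .month_num(m), dd) else ""
    # GEO accessions live in the DataBankList of the article
    acc <- all_txt(".//DataBankList/DataBank/AccessionNumberList/AccessionNumber")
    mesh_ui <- xml2::xml_attr(
      xml2::xml_find_all(a, ".//MeshHeadingList/MeshHeading/DescriptorName"), "UI")
    mesh_nm <- all_txt(".//MeshHeadingList/MeshHeading/DescriptorName")
    mesh <- ifelse(is.na(mesh_ui) | !nzchar(mesh_ui), mesh_nm, mesh_ui)
    list(pmid = txt(".//MedlineCitation/PMID"),
         title = txt(".//Article/ArticleTitle"),
         authors = authors,
         journal = txt(".//Article/Journal/Title"),
         pub_date = pub_date,
         mesh_headings = mesh,
         gse_codes = unique(grep("^GSE[0-9]+$", acc, value = TRUE)),
         platforms = unique(grep("^GPL[0-9]+$", acc, value = TRUE)),
         ftp_links = character(), analyses = character())
  })
}

.month_num <- function(m) {
  if (!nzchar(m)) return(1L)
  n <- suppressWarnings(as.integer(m))
  if (!is.na(n)) return(n)
  match(tolower(substr(m, 1, 3)),
        c("jan","feb","mar","apr","may","jun","jul","aug","sep","oct","nov","dec"),
        nomatch = 1L)
}

#' Build a corpus from an ordered PMID list
#'
#' @param pmids non-empty character vector; the corpus keeps this order.
#' @param fetcher function(pmid) returning a record field list or `NULL`
#'   when the pmid cannot be resolved (a live retrieval adapter or a
#'   fixture store, see [fixture_fetcher()]).
#' @return a `corpus`; unresolvable pmids are reported via a warning and
#'   the `unresolved` attribute.
#' @export
build_corpus_from_pmids <- function(pmids, fetcher, query = "", source_tag = "pmid-list") {
  if (length(pmids) == 0L) stop("pmid list is empty")
  pmids <- as.character(pmids)
  hits <- lapply(pmids, fetcher)
  miss <- pmids[vapply(hits, is.null, TRUE)]
  if (length(miss) == length(pmids)) stop("no pmid could be resolved")
  if (length(miss))
    warning("unresolved pmid(s): ", paste(miss, collapse = ", "))
  records <- lapply(hits[!vapply(hits, is.null, TRUE)], .new_record)
  out <- .new_corpus(records, query = query, source_tag = source_tag)
  attr(out, "unresolved") <- miss
  out
}

#' Fetcher over an in-memory corpus (offline fixture store)
#' @export
fixture_fetcher <- function(corpus) {
  idx <- stats::setNames(seq_along(corpus$records), corpus_pmids(corpus))
  function(pmid) {
    i <- idx[pmid]
    if (is.na(i)) NULL else corpus$records[[i]]
  }
}

#' Harvest GEO series accessions from free text
#'
#' Every substring matching `GSE[0-9]+` is captured once, in order of
#' first appearance.
#'
#' @param x character vector of raw link/text fields.
#' @return character vector of GSE accessions (possibly empty).
#' @export
extract_gse_links <- function(x) {
  m <- regmatches(x, gregexpr("GSE[0-9]+", x))
  unique(unlist(m, use.names = FALSE))
}

#' Corpus-wide MeSH term counts
#'
#' A term's count is the number of distinct records annotated with it; a
#' heading repeated within one record contributes once.
#'
#' @return named integer vector, term -> article count (empty for an
#'   empty corpus).
#' @export
mesh_term_counts <- function(corpus) {
  terms <- unlist(lapply(corpus$records,
                         function(r) unique(r$mesh_headings)),
                  use.names = FALSE)
  if (length(terms) == 0L) return(stats::setNames(integer(), character()))
  tab <- table(terms)
  stats::setNames(as.integer(tab), names(tab))
}

#' Keep the first n records in retrieval order
#' @export
limit_corpus <- function(corpus, n) {
  stopifnot(n >= 1)
  corpus$records <- corpus$records[seq_len(min(n, length(corpus$records)))]
  corpus
}

#' Write a corpus
#'
#' `"json"` emits JSON-lines that round-trip all metadata fields exactly;
#' `"tsv"` emits one row per record with list fields semicolon-joined.
#' @export
write_corpus <- function(corpus, path, dialect = c("json", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "json") {
    lines <- vapply(corpus$records, function(r)
      jsonlite::toJSON(r, auto_unbox = FALSE), "")
    writeLines(lines, path)
  } else {
    rows <- lapply(corpus$records, function(r) {
      vapply(.record_fields, function(f)
        if (f %in% .list_fields) paste(r[[f]], collapse = ";") else r[[f]], "")
    })
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- .record_fields
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
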