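rec <- function(pmid, heads = character(), ...) {
  c(list(pmid = pmid, title = paste("study", pmid),
         authors = c("Doe J"), journal = "J Test",
         pub_date = "2020-01-02", mesh_headings = heads),
    list(...))
}

test_that("JSON-lines records parse in order and round-trip exactly", {
  cp <- jsonl_corpus(list(rec("1", c("T1", "T2"), gse_codes = "GSE5"),
                          rec("2", "T1"), rec("3", "T3")))
  expect_s3_class(cp, "corpus")
  expect_length(cp, 3L)
  expect_equal(vapply(cp$records, `[[`, "", "pmid"), c("1", "2", "3"))

  tf <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(cp, tf, "json")
  cp2 <- parse_records(tf, "json")
  expect_equal(cp2$records, cp$records)
})

test_that("records without pmid are rejected; duplicate pmids drop with warning", {
  tf <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"pmid":["1"],"title":["a"]}',
               '{"title":["no id"]}',
               '{"pmid":["1"],"title":["dup"]}'), tf)
  expect_warning(expect_warning(cp <- parse_records(tf, "json"),
                                "without pmid"), "duplicated pmid")
  expect_length(cp, 1L)
  expect_equal(cp$records[[1L]]$title, "a")
  # missing optional fields become empty
  expect_equal(cp$records[[1L]]$mesh_headings, character())
})

test_that("MEDLINE XML parses the metadata block including GEO accessions", {
  xml <- '<?xml version="1.0"?>
<PubmedArticleSet>
 <PubmedArticle><MedlineCitation><PMID>101</PMID>
  <Article>
   <Journal><Title>J Fixture</Title>
    <JournalIssue><PubDate><Year>2019</Year><Month>Mar</Month><Day>4</Day></PubDate></JournalIssue>
   </Journal>
   <ArticleTitle>A fixture study</ArticleTitle>
   <AuthorList><Author><LastName>Smith</LastName><Initials>A</Initials></Author></AuthorList>
   <DataBankList><DataBank><DataBankName>GEO</DataBankName>
    <AccessionNumberList><AccessionNumber>GSE102484</AccessionNumber>
     <AccessionNumber>GPL570</AccessionNumber></AccessionNumberList>
   </DataBank></DataBankList>
  </Article>
  <MeshHeadingList>
   <MeshHeading><DescriptorName UI="D001943">Breast Neoplasms</DescriptorName></MeshHeading>
   <MeshHeading><DescriptorName>Humans</DescriptorName></MeshHeading>
  </MeshHeadingList>
 </MedlineCitation></PubmedArticle>
</PubmedArticleSet>'
  tf <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, tf)
  cp <- parse_records(tf, "medline-xml")
  r <- cp$records[[1L]]
  expect_equal(r$pmid, "101")
  expect_equal(r$journal, "J Fixture")
  expect_equal(r$pub_date, "2019-03-04")
  expect_equal(r$authors, "Smith A")
  expect_equal(r$mesh_headings, c("D001943", "Humans"))
  expect_equal(r$gse_codes, "GSE102484")
  expect_equal(r$platforms, "GPL570")
})

test_that("corpus builds from a pmid list via the fetcher contract", {
  store <- jsonl_corpus(list(rec("10"), rec("11"), rec("12")))
  fetch <- fixture_fetcher(store)
  cp <- build_corpus_from_pmids(c("12", "10"), fetch)
  expect_equal(vapply(cp$records, `[[`, "", "pmid"), c("12", "10"))
  expect_warning(cp2 <- build_corpus_from_pmids(c("10", "99", "11"), fetch),
                 "unresolved pmid.*99")
  expect_length(cp2, 2L)
  expect_equal(attr(cp2, "unresolved"), "99")
  expect_error(build_corpus_from_pmids(character(), fetch), "empty")
  expect_error(build_corpus_from_pmids(c("98", "99"), fetch),
               "no pmid could be resolved")
})

test_that("GSE links are harvested uniquely in order of first appearance", {
  expect_equal(extract_gse_links("data deposited as GSE102484"), "GSE102484")
  expect_equal(extract_gse_links("GSE5 and GSE5 again"), "GSE5")
  expect_equal(extract_gse_links("GPL570 only"), character())
  expect_equal(extract_gse_links(c("see GSE7, GSE3", "also GSE7")),
               c("GSE7", "GSE3"))
  # output is always built from substrings of the input
  x <- "mix GSE12 text GSE999"
  expect_true(all(vapply(extract_gse_links(x), grepl, TRUE, x = x, fixed = TRUE)))
})

test_that("MeSH counts are per distinct record", {
  cp <- jsonl_corpus(list(rec("1", c("T1", "T2")), rec("2", "T1"),
                          rec("3", "T3")))
  expect_equal(mesh_term_counts(cp), c(T1 = 2L, T2 = 1L, T3 = 1L))
  empty <- jsonl_corpus(list(rec("1")))
  expect_length(mesh_term_counts(empty), 0L)
  dup <- jsonl_corpus(list(rec("1", c("T1", "T1"))))
  expect_equal(mesh_term_counts(dup), c(T1 = 1L))
  # totals equal the sum of per-record distinct heading counts
  cp2 <- jsonl_corpus(list(rec("1", c("a", "b", "b")), rec("2", c("b", "c"))))
  expect_equal(sum(mesh_term_counts(cp2)),
               sum(vapply(cp2$records, function(r)
                 length(unique(r$mesh_headings)), 0L)))
})

test_that("limiting keeps the first n records in retrieval order", {
  cp <- jsonl_corpus(lapply(as.character(1:5), rec))
  expect_equal(vapply(limit_corpus(cp, 2)$records, `[[`, "", "pmid"),
               c("1", "2"))
  expect_length(limit_corpus(cp, 10), 5L)
  expect_error(limit_corpus(cp, 0))
})

test_that("invalid accession patterns are rejected at record construction", {
  tf <- withr::local_tempfile()
  writeLines('{"pmid":["1"],"gse_codes":["GSEx1"]}', tf)
  expect_warning(cp <- parse_records(tf, "json"), "invalid GSE")
  expect_length(cp, 0L)
  tf2 <- withr::local_tempfile()
  writeLines('{"pmid":["1"],"pub_date":["2020-13-40"]}', tf2)
  expect_warning(cp2 <- parse_records(tf2, "json"), "yyyy-mm-dd")
})
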