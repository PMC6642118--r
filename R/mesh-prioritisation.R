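# Three-criteria prioritisation of a corpus's MeSH annotations, fused by
# Robust Rank Aggregation (RRA): terms ranked consistently well across
# hierarchical specificity, corpus abundance and global rarity get small
# rho scores; Bonferroni correction multiplies by the number of lists.

.ranked_list <- function(criterion, ordering) {
  if (anyDuplicated(ordering)) stop("ranked list has duplicate terms")
  structure(list(criterion = criterion, ordering = ordering,
                 n = length(ordering)),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat("ranked list [", x$criterion, "], ", x$n, " terms\n", sep = "")
  invisible(x)
}

# stable sort: primary key, ties broken by label ascending
.order_with_labels <- function(key, labels, decreasing = FALSE) {
  order(if (decreasing) -xtfrm(key) else xtfrm(key), labels)
}

#' Rank terms by hierarchical specificity
#'
#' Deeper descriptors (deepest placement) rank first; ties broken by
#' descriptor name ascending. Terms not resolvable in the tree are
#' excluded and reported in the `excluded` attribute.
#'
#' @param terms character vector of descriptor UIs.
#' @param tree a `mesh_tree`.
#' @return a `ranked_list` with criterion `"specificity"`.
#' @export
rank_specificity <- function(terms, tree) {
  known <- terms[terms %in% names(tree$descriptors)]
  excluded <- setdiff(terms, known)
  if (length(excluded))
    warning("terms absent from vocabulary, excluded: ",
            paste(excluded, collapse = ", "))
  if (length(known) == 0L) stop("no term resolvable in the vocabulary")
  depths <- vapply(known, function(u) descriptor_depth(tree, u, "max"), 0L)
  nms <- mesh_names(tree, known)
  out <- .ranked_list("specificity", known[.order_with_labels(depths, nms, decreasing = TRUE)])
  attr(out, "excluded") <- excluded
  out
}

#' Rank terms by corpus abundance
#'
#' Higher corpus count ranks first; ties by label ascending.
#'
#' @param counts named numeric vector, term -> corpus article count.
#' @param labels optional named character vector mapping terms to display
#'   names used for tie-breaking (defaults to the term identifiers).
#' @export
rank_local_abundance <- function(counts, labels = NULL) {
  if (length(counts) == 0L) stop("empty count table")
  terms <- names(counts)
  lab <- if (is.null(labels)) terms else ifelse(is.na(labels[terms]), terms, labels[terms])
  .ranked_list("local_abundance",
               terms[.order_with_labels(as.numeric(counts), lab, decreasing = TRUE)])
}

#' Rank terms by global rarity
#'
#' Terms that are rare over the whole citation database rank first
#' (background count ascending); ties by label. Terms missing from the
#' background are imputed at the background median and reported.
#'
#' @param terms character vector of term identifiers.
#' @param background named numeric vector, term -> database-wide count.
#' @export
rank_global_abundance <- function(terms, background, labels = NULL) {
  if (length(background) == 0L) stop("empty background table")
  cnt <- background[terms]
  names(cnt) <- terms
  miss <- terms[is.na(cnt)]
  if (length(miss)) {
    warning("terms missing from background, imputed at median: ",
            paste(miss, collapse = ", "))
    cnt[miss] <- stats::median(as.numeric(background))
  }
  lab <- if (is.null(labels)) terms else ifelse(is.na(labels[terms]), terms, labels[terms])
  out <- .ranked_list("global_abundance",
                      terms[.order_with_labels(as.numeric(cnt), lab)])
  attr(out, "imputed") <- miss
  out
}

#' Normalised rank vectors over a term universe
#'
#' A term at 1-based position i in a list of size N has normalised rank
#' i/N; a term absent from a list gets 1.0 (the conservative worst rank).
#'
#' @param lists list of `ranked_list` objects.
#' @param universe character vector of terms (rows of the result).
#' @return numeric matrix, terms x lists, entries in (0, 1].
#' @export
normalize_ranks <- function(lists, universe) {
  r <- matrix(1.0, nrow = length(universe), ncol = length(lists),
              dimnames = list(universe,
                              vapply(lists, `[[`, "", "criterion")))
  for (j in seq_along(lists)) {
    l <- lists[[j]]
    pos <- match(universe, l$ordering)
    ok <- !is.na(pos)
    r[ok, j] <- pos[ok] / l$n
  }
  r
}

#' Robust Rank Aggregation score of one rank vector
#'
#' With the normalised ranks sorted ascending r_(1) <= ... <= r_(n), the
#' k-th beta-score is the upper binomial tail P(X >= k), X ~
#' Binomial(n, r_(k)): the probability that at least k of n uniform null
#' ranks fall at or below r_(k). rho is the minimum beta-score and the
#' corrected score is min(1, rho * n) (Bonferroni over the n order
#' statistics).
#'
#' @param r numeric vector of normalised ranks, each in (0, 1].
#' @return list with `rho`, `p_corrected`, `k_min` (index of the
#'   minimising order statistic) and `beta` (all n beta-scores).
#' @export
rra_score <- function(r) {
  if (length(r) == 0L || any(r <= 0 | r > 1))
    stop("normalised ranks must lie in (0, 1]")
  n <- length(r)
  rs <- sort(r)
  beta <- stats::pbinom(seq_len(n) - 1L, n, rs, lower.tail = FALSE)
  k <- which.min(beta)
  list(rho = beta[[k]], p_corrected = min(1, beta[[k]] * n),
       k_min = k, beta = beta)
}

# vectorised rho over rows of a rank matrix (used by prioritise and the
# null-calibration checks); identical to rra_score row-wise
.rra_rho_rows <- function(R) {
  n <- ncol(R)
  Rs <- t(apply(R, 1L, sort))
  if (n == 1L) Rs <- matrix(R, ncol = 1L)
  beta <- vapply(seq_len(n), function(k)
    stats::pbinom(k - 1L, n, Rs[, k], lower.tail = FALSE),
    numeric(nrow(R)))
  if (nrow(R) == 1L) beta <- matrix(beta, nrow = 1L)
  list(rho = apply(beta, 1L, min), k_min = apply(beta, 1L, which.min),
       beta = beta)
}

#' Prioritise a corpus's MeSH terms
#'
#' The term universe is the union of MeSH annotations over the corpus
#' (aggregated as descriptor UIs). Three rankings are built -- deepest
#' placement (specificity, descending), corpus abundance (descending),
#' global background abundance (ascending: globally rare is better) --
#' normalised, and fused with [rra_score()]. The output is sorted by
#' corrected score ascending, ties by rho then name.
#'
#' @param corpus a `corpus` whose records carry MeSH headings.
#' @param tree a `mesh_tree`.
#' @param background named numeric vector, ui -> database-wide count.
#' @return data.frame (class `mesh_priority`) with columns ui, name,
#'   depth, local_count, global_count, r_specificity, r_local, r_global,
#'   rho, p_corrected, k_min.
#' @export
prioritise <- function(corpus, tree, background) {
  counts_raw <- mesh_term_counts(corpus)
  if (length(counts_raw) == 0L) stop("corpus carries no MeSH headings")
  uis <- resolve_terms(tree, names(counts_raw))
  # corpus counts keyed by ui (headings may arrive as names)
  by_name <- .mesh_name_index(tree)
  key <- ifelse(names(counts_raw) %in% names(tree$descriptors),
                names(counts_raw), unname(by_name[names(counts_raw)]))
  counts <- stats::setNames(as.integer(counts_raw), key)
  counts <- counts[!is.na(names(counts))]
  counts <- tapply(counts, names(counts), sum)  # name+ui duplicates merge
  universe <- sort(unique(names(counts)))
  if (length(universe) == 0L) stop("no corpus MeSH heading resolvable in the vocabulary")
  labels <- mesh_names(tree, universe)

  l_spec <- rank_specificity(universe, tree)
  l_loc <- rank_local_abundance(counts[universe], labels = labels)
  glob <- suppressWarnings(rank_global_abundance(universe, background, labels = labels))
  R <- normalize_ranks(list(l_spec, l_loc, glob), universe)
  sc <- .rra_rho_rows(R)
  p_corr <- pmin(1, sc$rho * ncol(R))

  bg <- background[universe]
  bg[is.na(bg)] <- stats::median(as.numeric(background))
  out <- data.frame(
    ui = universe,
    name = unname(labels),
    depth = vapply(universe, function(u) descriptor_depth(tree, u, "max"), 0L),
    local_count = as.integer(counts[universe]),
    global_count = as.numeric(bg),
    r_specificity = R[, 1L], r_local = R[, 2L], r_global = R[, 3L],
    rho = sc$rho, p_corrected = p_corr, k_min = as.integer(sc$k_min),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p_corrected, out$rho, out$name), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mesh_priority", "data.frame")
  out
}

#' Write a prioritised-terms table as TSV
#' @export
write_priority <- function(priority, path) {
  utils::write.table(as.data.frame(priority), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
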