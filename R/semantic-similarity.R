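# Six MeSH term similarity measures, each normalised to [0,1]. Five are
# path-based over the placement forest (shortest-path, weighted-link,
# Wu-Palmer, Leacock-Chodorow, Li); Lord's measure is information-based
# and needs a table of cumulative term occurrence counts.

.sim_measures <- c("shortest_path", "weighted_link", "wu_palmer",
                   "leacock_chodorow", "li", "lord")

#' Similarity configuration
#'
#' @param li_alpha path-decay constant of the Li measure (default 0.2).
#' @param li_beta depth-saturation constant of the Li measure (default 0.6).
#' @param ic_table named numeric vector, ui -> cumulative occurrence
#'   count (each node's count includes all of its descendants'); required
#'   by the Lord measure. See [ic_cumulative()].
#' @export
similarity_config <- function(li_alpha = 0.2, li_beta = 0.6, ic_table = NULL) {
  stopifnot(li_alpha >= 0, li_beta > 0)
  if (!is.null(ic_table) && (length(ic_table) == 0L || sum(ic_table) <= 0))
    stop("ic_table must carry positive total mass")
  structure(list(li_alpha = li_alpha, li_beta = li_beta, ic_table = ic_table),
            class = "similarity_config")
}

#' Cumulative occurrence counts for the Lord measure
#'
#' Turns raw per-descriptor occurrence counts into cumulative counts in
#' which every descriptor's mass includes all of its descendants'
#' (summed over placements; a multi-placement descendant contributes to
#' each of its ancestor chains).
#'
#' @param tree a `mesh_tree`.
#' @param counts named numeric vector, ui -> raw count; descriptors
#'   absent from `counts` get 0.
#' @return named numeric vector, ui -> cumulative count.
#' @export
ic_cumulative <- function(tree, counts) {
  uis <- names(tree$descriptors)
  raw <- stats::setNames(rep(0, length(uis)), uis)
  hit <- intersect(names(counts), uis)
  raw[hit] <- as.numeric(counts[hit])
  positions <- names(tree$position_index)
  vapply(uis, function(u) {
    ps <- tree$descriptors[[u]]$tree_numbers
    under <- positions[vapply(positions, function(q)
      any(q == ps | startsWith(q, paste0(ps, "."))), TRUE)]
    # each descendant descriptor contributes its mass once
    sum(raw[unique(unname(tree$position_index[under]))])
  }, 0)
}

#' Shortest-path similarity
#'
#' `1 - l / (2 * max_depth)` with l the placement-pair-minimised path
#' length in edges, floored at 0. Identity scores exactly 1.
#' @export
sim_shortest_path <- function(tree, a, b) {
  l <- shortest_path_edges(tree, a, b)
  max(0, 1 - l / (2 * tree$max_depth))
}

#' Wu-Palmer similarity
#'
#' `2 * depth(lca) / (depth(a) + depth(b))` over the placement pair whose
#' common ancestor is deepest; 0 when the two descriptors only meet at
#' the virtual root.
#' @export
sim_wu_palmer <- function(tree, a, b) {
  lca <- mesh_lca(tree, a, b)
  if (lca$depth == 0L) return(0)
  2 * lca$depth / sum(lca$pair_depths)
}

#' Leacock-Chodorow similarity
#'
#' `-ln(l_nodes / (2 * max_depth)) / ln(2 * max_depth)` with the path
#' counted in nodes (edges + 1) so the identity case is finite and maps
#' to exactly 1; a maximally distant pair (l_nodes = 2 * max_depth) maps
#' to 0.
#' @export
sim_leacock_chodorow <- function(tree, a, b) {
  stopifnot(tree$max_depth >= 1)
  l_nodes <- shortest_path_edges(tree, a, b) + 1L
  max(0, -log(l_nodes / (2 * tree$max_depth)) / log(2 * tree$max_depth))
}

#' Li similarity
#'
#' `exp(-alpha * l) * tanh(beta * h)` with l the shortest path in edges
#' and h the depth of the lowest common ancestor. Inherent to the
#' measure, the identity value tanh(beta * depth) is below 1.
#' @export
sim_li <- function(tree, a, b, config = similarity_config()) {
  l <- shortest_path_edges(tree, a, b)
  h <- mesh_lca(tree, a, b)$depth
  exp(-config$li_alpha * l) * tanh(config$li_beta * h)
}

#' Lord (information content) similarity
#'
#' p(c) = cum_count(c) / total; IC(c) = -ln p(c). The score is
#' IC(MICA) / max(IC(a), IC(b)), where the MICA is the common ancestor
#' of the pair maximising IC (a term is its own ancestor, so the
#' identity scores exactly 1); 0 when the only common ancestor is the
#' virtual root. Because cumulative counts are monotone along the
#' hierarchy the score stays in [0, 1], and it is invariant to
#' rescaling all counts by a positive constant.
#' @export
sim_lord <- function(tree, a, b, config) {
  ic <- config$ic_table
  if (is.null(ic) || sum(ic) <= 0) stop("Lord similarity needs an ic_table with positive mass")
  .check_ui(tree, a); .check_ui(tree, b)
  # total mass = cumulative mass of the category roots (depth-1 positions)
  roots <- names(tree$position_index)[!grepl(".", names(tree$position_index), fixed = TRUE)]
  total <- sum(as.numeric(ic[unique(unname(tree$position_index[roots]))]), na.rm = TRUE)
  if (total <= 0) stop("ic_table has no mass at the category roots")
  ic_of <- function(uis) {
    p <- as.numeric(ic[uis]) / total
    p[is.na(p) | p <= 0] <- 1  # untabled or unobserved: uninformative
    -log(p)
  }
  anc <- function(ui) unique(unlist(lapply(tree$descriptors[[ui]]$tree_numbers,
                                           .ancestor_positions), use.names = FALSE))
  common <- intersect(anc(a), anc(b))  # includes self placements
  if (length(common) == 0L) return(0)
  mica_ic <- max(ic_of(unique(unname(tree$position_index[common]))))
  denom <- max(ic_of(c(a, b)))
  if (denom <= 0) return(if (a == b) 1 else 0)  # both terms carry full mass
  min(1, mica_ic / denom)
}

.ancestor_positions <- function(code) {
  f <- .code_fields(code)
  vapply(seq_along(f), function(k) paste(f[seq_len(k)], collapse = "."), "")
}

#' Weighted-link similarity
#'
#' Each edge entering a node at depth d weighs 2^-d; the weighted
#' distance L is minimised over placement pairs and the score is
#' `1 - L / L_max` with `L_max = 2 * sum_{d=1..max_depth} 2^-d` (twice a
#' full root-to-leaf descent). Deeper siblings score higher than shallow
#' ones because deep edges are cheap.
#' @export
sim_weighted_link <- function(tree, a, b) {
  .check_ui(tree, a); .check_ui(tree, b)
  L <- .weighted_path_length(tree, a, b)
  L_max <- 2 * sum(2^-(seq_len(tree$max_depth)))
  max(0, 1 - L / L_max)
}

#' Term-to-term similarity under a named measure
#'
#' @param measure one of `shortest_path`, `weighted_link`, `wu_palmer`,
#'   `leacock_chodorow`, `li`, `lord`.
#' @export
mesh_similarity <- function(tree, a, b,
                            measure = c("shortest_path", "weighted_link",
                                        "wu_palmer", "leacock_chodorow",
                                        "li", "lord"),
                            config = similarity_config()) {
  measure <- match.arg(measure)
  .check_ui(tree, a); .check_ui(tree, b)
  switch(measure,
         shortest_path = sim_shortest_path(tree, a, b),
         weighted_link = sim_weighted_link(tree, a, b),
         wu_palmer = sim_wu_palmer(tree, a, b),
         leacock_chodorow = sim_leacock_chodorow(tree, a, b),
         li = sim_li(tree, a, b, config),
         lord = sim_lord(tree, a, b, config))
}

#' Set-versus-set similarity (best-match average)
#'
#' Each term is matched to its best counterpart in the other set and the
#' best-match scores are averaged over both directions:
#' `(sum_a max_b s(a,b) + sum_b max_a s(a,b)) / (|A| + |B|)`.
#' Terms (UIs or names) not resolvable in the tree are excluded and
#' reported; an empty set after resolution is an error.
#' @export
set_similarity <- function(tree, set_a, set_b,
                           measure = "shortest_path",
                           config = similarity_config()) {
  A <- resolve_terms(tree, set_a)
  B <- resolve_terms(tree, set_b)
  dropped <- c(attr(A, "unresolved"), attr(B, "unresolved"))
  if (length(dropped))
    warning("unresolvable terms excluded: ", paste(unique(dropped), collapse = ", "))
  if (length(A) == 0L || length(B) == 0L)
    stop("term set empty after resolution")
  S <- matrix(0, length(A), length(B))
  for (i in seq_along(A))
    for (j in seq_along(B))
      S[i, j] <- mesh_similarity(tree, A[[i]], B[[j]], measure, config)
  (sum(apply(S, 1L, max)) + sum(apply(S, 2L, max))) / (length(A) + length(B))
}

#' Significance flag for a similarity score
#'
#' Scores are read as the probability that two term sets are similar;
#' 0.5 is the conventional minimum threshold and the comparison is
#' inclusive.
#' @export
significance_flag <- function(score) {
  if (is.na(score) || score < 0 || score > 1)
    stop("similarity score must lie in [0, 1]")
  score >= 0.5
}
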