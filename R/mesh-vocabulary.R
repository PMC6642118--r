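# tree numbers are dot-separated position codes, e.g. "C04.557.470"
.tree_number_rx <- "^[A-Z][0-9]{2}(\\.[0-9]{3})*$"

#' Parse a MeSH vocabulary into a queryable tree
#'
#' Reads a controlled vocabulary in which each descriptor carries one or
#' more tree numbers (dot-separated position codes) and may therefore sit
#' at several places in the hierarchy. Two dialects are supported: the
#' MeSH ASCII descriptor format (records of `MH =` / `UI =` / `MN =`
#' lines separated by blank lines) and a three-column TSV
#' (`ui`, `name`, semicolon-joined tree numbers, no header).
#'
#' @param source path to the vocabulary file.
#' @param dialect `"tsv"` or `"mesh-ascii"`.
#' @return an object of class `mesh_tree`: a list with `descriptors`
#'   (named list, ui -> list(ui, name, tree_numbers)), `position_index`
#'   (named character, tree number -> ui) and `max_depth`.
#' @export
parse_mesh <- function(source, dialect = c("tsv", "mesh-ascii")) {
  dialect <- match.arg(dialect)
  lines <- readLines(source, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) | dialect == "mesh-ascii"]
  recs <- if (dialect == "tsv") .parse_mesh_tsv(lines) else .parse_mesh_ascii(lines)
  if (length(recs) == 0L) stop("empty vocabulary")
  uis <- vapply(recs, `[[`, "", "ui")
  dup <- uis[duplicated(uis)]
  if (length(dup)) stop("duplicate descriptor ui: ", paste(unique(dup), collapse = ", "))
  for (r in recs) {
    bad <- r$tree_numbers[!grepl(.tree_number_rx, r$tree_numbers)]
    if (length(bad)) stop("malformed tree number '", bad[[1L]], "' for ", r$ui)
    if (length(r$tree_numbers) == 0L) stop("descriptor ", r$ui, " has no tree number")
  }
  names(recs) <- uis
  positions <- unlist(lapply(recs, `[[`, "tree_numbers"), use.names = FALSE)
  owner <- rep(uis, vapply(recs, function(r) length(r$tree_numbers), 0L))
  if (anyDuplicated(positions))
    stop("tree number indexed twice: ",
         paste(unique(positions[duplicated(positions)]), collapse = ", "))
  position_index <- stats::setNames(owner, positions)
  # every non-top code must have its parent prefix present
  for (p in positions) {
    parent <- .parent_code(p)
    if (!is.na(parent) && !parent %in% positions)
      stop("orphan tree number '", p, "': parent '", parent, "' absent")
  }
  tree <- structure(
    list(descriptors = recs,
         position_index = position_index,
         max_depth = max(vapply(positions, .code_depth, 0L))),
    class = "mesh_tree")
  tree
}

.parse_mesh_tsv <- function(lines) {
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  lapply(fields, function(f) {
    if (length(f) < 3L) stop("TSV vocabulary row needs 3 columns: ", paste(f, collapse = "\t"))
    tn <- trimws(strsplit(f[[3L]], ";", fixed = TRUE)[[1L]])
    list(ui = trimws(f[[1L]]), name = .unquote(trimws(f[[2L]])),
         tree_numbers = tn[nzchar(tn)])
  })
}

.parse_mesh_ascii <- function(lines) {
  recs <- list()
  cur <- NULL
  flush <- function(cur, recs) {
    if (!is.null(cur) && (nzchar(cur$ui %||% "") || length(cur$tree_numbers)))
      recs[[length(recs) + 1L]] <- cur
    recs
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) { recs <- flush(cur, recs); cur <- NULL; next }
    if (grepl("^\\*NEWRECORD", ln)) { recs <- flush(cur, recs); cur <- NULL; next }
    m <- regmatches(ln, regexec("^([A-Z]+) = (.*)$", ln))[[1L]]
    if (length(m) != 3L) next
    if (is.null(cur)) cur <- list(ui = "", name = "", tree_numbers = character())
    val <- trimws(m[[3L]])
    cur <- switch(m[[2L]],
      MH = { cur$name <- val; cur },
      UI = { cur$ui <- val; cur },
      MN = { cur$tree_numbers <- c(cur$tree_numbers, val); cur },
      cur)
  }
  flush(cur, recs)
}

.unquote <- function(x) sub('^"(.*)"$', "\\1", x)

`%||%` <- function(a, b) if (is.null(a)) b else a

.code_fields <- function(code) strsplit(code, ".", fixed = TRUE)[[1L]]
.code_depth <- function(code) length(.code_fields(code))
.parent_code <- function(code) {
  f <- .code_fields(code)
  if (length(f) == 1L) NA_character_ else paste(f[-length(f)], collapse = ".")
}

#' @export
print.mesh_tree <- function(x, ...) {
  cat("MeSH tree: ", length(x$descriptors), " descriptors, ",
      length(x$position_index), " placements, max depth ", x$max_depth, "\n", sep = "")
  invisible(x)
}

.check_ui <- function(tree, ui) {
  if (!ui %in% names(tree$descriptors)) stop("unknown descriptor ui: ", ui)
}

#' Depth of a tree position
#'
#' Depth is the number of dot-separated fields of the code ("C04" has
#' depth 1); a virtual root above all category-level codes has depth 0.
#'
#' @param tree a `mesh_tree`.
#' @param position a tree number present in the tree.
#' @return positive integer depth.
#' @export
mesh_depth <- function(tree, position) {
  if (!position %in% names(tree$position_index))
    stop("unknown tree position: ", position)
  .code_depth(position)
}

#' Depth of a descriptor across its placements
#'
#' @param tree a `mesh_tree`.
#' @param ui descriptor identifier.
#' @param mode `"max"` (deepest placement; the specificity convention) or
#'   `"min"` (shallowest).
#' @return positive integer.
#' @export
descriptor_depth <- function(tree, ui, mode = c("max", "min")) {
  mode <- match.arg(mode)
  .check_ui(tree, ui)
  d <- vapply(tree$descriptors[[ui]]$tree_numbers, .code_depth, 0L)
  if (mode == "max") max(d) else min(d)
}

.common_prefix_depth <- function(fa, fb) {
  k <- 0L
  for (i in seq_len(min(length(fa), length(fb)))) {
    if (fa[[i]] != fb[[i]]) break
    k <- i
  }
  k
}

#' Lowest common ancestor of two descriptors
#'
#' Over all pairs of placements of the two descriptors, returns the
#' common-prefix ancestor of maximum depth. Placements in disjoint
#' categories meet only at the virtual root (depth 0, position `NA`).
#' `mesh_lca(tree, x, x)` is x's deepest placement.
#'
#' @return list with `position` (tree number or `NA` for the virtual
#'   root), `depth`, and `pair_depths` (the depths of the two placements
#'   achieving it; among ties the shallowest pair is kept).
#' @export
mesh_lca <- function(tree, ui_a, ui_b) {
  .check_ui(tree, ui_a); .check_ui(tree, ui_b)
  pa <- tree$descriptors[[ui_a]]$tree_numbers
  pb <- tree$descriptors[[ui_b]]$tree_numbers
  best <- list(position = NA_character_, depth = 0L,
               pair_depths = c(min(vapply(pa, .code_depth, 0L)),
                               min(vapply(pb, .code_depth, 0L))))
  for (a in pa) {
    fa <- .code_fields(a)
    for (b in pb) {
      fb <- .code_fields(b)
      k <- .common_prefix_depth(fa, fb)
      cand <- c(length(fa), length(fb))
      if (k > best$depth || (k == best$depth && k > 0L && sum(cand) < sum(best$pair_depths))) {
        best <- list(
          position = if (k == 0L) NA_character_ else paste(fa[seq_len(k)], collapse = "."),
          depth = k, pair_depths = cand)
      }
    }
  }
  best
}

#' Shortest path between two descriptors, in edges
#'
#' Minimised over all placement pairs:
#' `(depth(a) - depth(lca)) + (depth(b) - depth(lca))` for the pair's
#' common-prefix ancestor; paths through the virtual root are allowed, so
#' descriptors in disjoint categories are still connected.
#'
#' @return non-negative integer; 0 for identical descriptors.
#' @export
shortest_path_edges <- function(tree, ui_a, ui_b) {
  .check_ui(tree, ui_a); .check_ui(tree, ui_b)
  pa <- tree$descriptors[[ui_a]]$tree_numbers
  pb <- tree$descriptors[[ui_b]]$tree_numbers
  best <- Inf
  for (a in pa) {
    fa <- .code_fields(a)
    for (b in pb) {
      fb <- .code_fields(b)
      k <- .common_prefix_depth(fa, fb)
      best <- min(best, (length(fa) - k) + (length(fb) - k))
    }
  }
  as.integer(best)
}

# weighted path length: an edge entering a node at depth d weighs 2^-d;
# virtual-root -> category edges are at depth 1
.weighted_path_length <- function(tree, ui_a, ui_b) {
  pa <- tree$descriptors[[ui_a]]$tree_numbers
  pb <- tree$descriptors[[ui_b]]$tree_numbers
  seg <- function(from_depth, to_depth) {
    if (to_depth <= from_depth) return(0)
    sum(2^-(seq.int(from_depth + 1L, to_depth)))
  }
  best <- Inf
  for (a in pa) {
    fa <- .code_fields(a)
    for (b in pb) {
      fb <- .code_fields(b)
      k <- .common_prefix_depth(fa, fb)
      best <- min(best, seg(k, length(fa)) + seg(k, length(fb)))
    }
  }
  best
}

# name -> ui lookup table for a tree
.mesh_name_index <- function(tree) {
  stats::setNames(names(tree$descriptors),
                  vapply(tree$descriptors, `[[`, "", "name"))
}

#' Resolve term identifiers against a vocabulary
#'
#' Terms may be descriptor UIs or preferred names; returns the UIs of the
#' resolvable terms and reports the rest.
#'
#' @return character vector of UIs with attribute `unresolved`.
#' @export
resolve_terms <- function(tree, terms) {
  by_name <- .mesh_name_index(tree)
  ui <- ifelse(terms %in% names(tree$descriptors), terms,
               unname(by_name[terms]))
  out <- unique(ui[!is.na(ui)])
  attr(out, "unresolved") <- unique(terms[is.na(ui)])
  out
}

#' Descriptor preferred names
#' @return named character vector, ui -> name.
#' @export
mesh_names <- function(tree, uis = names(tree$descriptors)) {
  vapply(tree$descriptors[uis], `[[`, "", "name")
}
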