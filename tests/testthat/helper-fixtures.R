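# Shared fixtures and independent oracles, built in code at test time.

# five-descriptor toy tree: A=A01, B=A01.111, C=A01.111.222,
# D=A01.111.333, E=A01.444; max depth 3
toy_tree <- function() {
  tf <- withr::local_tempfile(fileext = ".tsv",
                              .local_envir = parent.frame())
  writeLines(c("DA\tA\tA01",
               "DB\tB\tA01.111",
               "DC\tC\tA01.111.222",
               "DD\tD\tA01.111.333",
               "DE\tE\tA01.444"), tf)
  parse_mesh(tf, "tsv")
}

# random multi-placement vocabulary written through the public parser
random_tree <- function(n, max_depth = 4L, seed = 1L, p_multi = 0.2) {
  set.seed(seed)
  cats <- c("A01", "B02")
  positions <- cats
  placements <- list(cats[[1L]], cats[[2L]])
  kid <- new.env(parent = emptyenv())
  child_of <- function(parent) {
    k <- (get0(parent, envir = kid, ifnotfound = 0L)) + 1L
    assign(parent, k, envir = kid)
    paste0(parent, ".", sprintf("%03d", k))
  }
  for (i in seq.int(3L, n)) {
    ok <- positions[lengths(strsplit(positions, ".", fixed = TRUE)) < max_depth]
    pos <- child_of(sample(ok, 1L))
    placements[[i]] <- pos
    positions <- c(positions, pos)
    if (stats::runif(1) < p_multi) {
      pos2 <- child_of(sample(ok, 1L))
      placements[[i]] <- c(placements[[i]], pos2)
      positions <- c(positions, pos2)
    }
  }
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf))
  writeLines(sprintf("T%03d\tname-%03d\t%s", seq_len(n), seq_len(n),
                     vapply(placements, paste, "", collapse = ";")), tf)
  parse_mesh(tf, "tsv")
}

# breadth-first-search distance over the undirected placement graph
# (positions + virtual root), minimised over the descriptors' placements
bfs_dist_oracle <- function(tree, a, b) {
  positions <- names(tree$position_index)
  nodes <- c("<root>", positions)
  parent_of <- function(p) {
    f <- strsplit(p, ".", fixed = TRUE)[[1L]]
    if (length(f) == 1L) "<root>" else paste(f[-length(f)], collapse = ".")
  }
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (p in positions) {
    q <- parent_of(p)
    adj[[p]] <- c(adj[[p]], q)
    adj[[q]] <- c(adj[[q]], p)
  }
  starts <- tree$descriptors[[a]]$tree_numbers
  goals <- tree$descriptors[[b]]$tree_numbers
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[starts] <- 0
  queue <- starts
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    for (nb in adj[[cur]]) {
      if (dist[[nb]] > dist[[cur]] + 1L) {
        dist[[nb]] <- dist[[cur]] + 1L
        queue <- c(queue, nb)
      }
    }
  }
  as.integer(min(dist[goals]))
}

# direct binomial-mass summation (no pbinom) for the RRA beta-scores
rra_oracle <- function(r) {
  n <- length(r)
  rs <- sort(r)
  beta <- vapply(seq_len(n), function(k) {
    p <- rs[[k]]
    sum(vapply(k:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j), 0))
  }, 0)
  k <- which.min(beta)
  list(rho = beta[[k]], p_corrected = min(1, beta[[k]] * n), k_min = k,
       beta = beta)
}

# independently coded three-criteria prioritiser (plain order() calls and
# the closed-form binomial tail), for oracle-equivalence checks
brute_prioritise <- function(corpus, tree, background) {
  heads <- lapply(corpus$records, function(r) unique(r$mesh_headings))
  counts <- table(unlist(heads))
  uis <- sort(intersect(names(counts), names(tree$descriptors)))
  nm <- vapply(tree$descriptors[uis], `[[`, "", "name")
  dep <- vapply(uis, function(u)
    max(lengths(strsplit(tree$descriptors[[u]]$tree_numbers, ".", fixed = TRUE))), 0L)
  loc <- as.integer(counts[uis])
  glob <- as.numeric(background[uis])
  glob[is.na(glob)] <- stats::median(as.numeric(background))
  rank_of <- function(ord) {
    # position of each ui in the ordering, normalised
    stats::setNames(match(uis, ord) / length(ord), uis)
  }
  r1 <- rank_of(uis[order(-dep, nm)])
  r2 <- rank_of(uis[order(-loc, nm)])
  r3 <- rank_of(uis[order(glob, nm)])
  sc <- t(vapply(uis, function(u) {
    r <- sort(c(r1[[u]], r2[[u]], r3[[u]]))
    beta <- vapply(1:3, function(k)
      sum(vapply(k:3, function(j) choose(3, j) * r[[k]]^j * (1 - r[[k]])^(3 - j), 0)), 0)
    c(rho = min(beta), p = min(1, 3 * min(beta)))
  }, c(rho = 0, p = 0)))
  out <- data.frame(ui = uis, name = nm, rho = sc[, "rho"], p = sc[, "p"],
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$rho, out$name), ]
  rownames(out) <- NULL
  out
}

# a ranked_list whose ordering is exactly `ordering`, via the public API
.ranked_list_for_test <- function(ordering)
  rank_local_abundance(stats::setNames(rev(seq_along(ordering)), ordering))

# corpus from a list of field lists, through the JSON-lines reader
jsonl_corpus <- function(records, query = "") {
  tf <- tempfile(fileext = ".jsonl")
  on.exit(unlink(tf))
  writeLines(vapply(records, function(r)
    as.character(jsonlite::toJSON(r, auto_unbox = FALSE)), ""), tf)
  parse_records(tf, "json", query = query)
}

# small series-matrix text built in code
write_toy_series <- function(path, edata, titles,
                             accession = "GSE1", na_token = "null") {
  q <- function(x) paste0('"', x, '"')
  samples <- colnames(edata)
  lines <- c(
    paste0("!Series_geo_accession\t", q(accession)),
    paste(c("!Sample_title", q(titles)), collapse = "\t"),
    paste(c("!Sample_geo_accession", q(samples)), collapse = "\t"),
    "!series_matrix_table_begin",
    paste(c(q("ID_REF"), q(samples)), collapse = "\t"))
  for (i in seq_len(nrow(edata))) {
    v <- edata[i, ]
    lines <- c(lines, paste(c(q(rownames(edata)[i]),
                              ifelse(is.na(v), na_token, format(v, trim = TRUE))),
                            collapse = "\t"))
  }
  writeLines(c(lines, "!series_matrix_table_end"), path)
  path
}

# naive O(n^3) complete-linkage agglomeration over sample columns
complete_linkage_oracle <- function(matrix) {
  d <- as.matrix(stats::dist(t(matrix)))
  clusters <- as.list(seq_len(ncol(matrix)))
  heights <- numeric()
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters))
      for (j in seq_len(i - 1L)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[[1L]]) best <- c(h, j, i)
      }
    heights <- c(heights, best[[1L]])
    merged <- c(clusters[[best[[2L]]]], clusters[[best[[3L]]]])
    clusters <- clusters[-c(best[[2L]], best[[3L]])]
    clusters[[length(clusters) + 1L]] <- merged
    partitions[[length(partitions) + 1L]] <-
      lapply(clusters, function(ix) sort(colnames(matrix)[ix]))
  }
  list(heights = heights, partitions = partitions)
}

# partition of samples implied by cutting an hclust at k clusters,
# as a canonical set of sets
canon_partition <- function(groups) {
  out <- lapply(split(names(groups), groups), sort)
  out[order(vapply(out, `[[`, "", 1L))]
}
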