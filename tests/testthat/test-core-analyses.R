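test_that("sample scores match a brute-force eigendecomposition", {
  set.seed(21)
  m <- matrix(rnorm(2 * 3), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  got <- expr_pca(m, k = 2)
  X <- t(m) - rep(rowMeans(m), each = 3)      # centred samples x genes
  eg <- eigen(stats::cov(X))
  scores <- X %*% eg$vectors
  # align the oracle's arbitrary signs to the package's convention
  for (j in 1:2) {
    v <- eg$vectors[, j]
    if (v[[which.max(abs(v))]] < 0) scores[, j] <- -scores[, j]
  }
  expect_equal(unname(got$scores), unname(scores[, 1:2]), tolerance = 1e-9)
  expect_equal(got$explained_ratio_all,
               eg$values / sum(eg$values), tolerance = 1e-9)
})

test_that("explained ratios are non-increasing and sum to one", {
  set.seed(8)
  m <- matrix(rnorm(30 * 6), nrow = 30,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:6)))
  p <- expr_pca(m, k = 4)
  expect_true(all(diff(p$explained_ratio_all) < 1e-12))
  expect_equal(sum(p$explained_ratio_all), 1, tolerance = 1e-9)
})

test_that("full-rank scores and loadings reconstruct the centred matrix", {
  set.seed(9)
  m <- matrix(rnorm(8 * 5), nrow = 8,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  p <- expr_pca(m, k = 5)
  centred <- t(m) - rep(rowMeans(m), each = 5)
  expect_equal(unname(p$scores %*% t(p$loadings)), unname(centred),
               tolerance = 1e-9)
})

test_that("duplicated samples coincide in score space; invalid k errors", {
  m <- matrix(c(1, 5, 1, 5, 3, 7), nrow = 2,
              dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  p <- expr_pca(m, k = 2)
  expect_equal(p$scores["a", ], p$scores["b", ], tolerance = 1e-12)
  expect_error(expr_pca(m, k = 3), "exceeds")
})

test_that("missing values are gene-mean imputed and counted", {
  m <- matrix(c(1, 2, 3, NA, 5, 7), nrow = 2,
              dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  p <- expr_pca(m, k = 2)
  expect_equal(p$n_imputed, 1L)
  expect_false(any(is.na(p$scores)))
})

test_that("top variable genes sort by variance then name, clamped at n", {
  m <- rbind(g_mid = c(0, 2, 4), g_hi = c(0, 5, 10), g_lo = c(1, 1, 2))
  colnames(m) <- paste0("s", 1:3)
  expect_equal(top_variable_genes(m, 2), c("g_hi", "g_mid"))
  expect_equal(top_variable_genes(m, 100), c("g_hi", "g_mid", "g_lo"))
  flat <- rbind(m, g_const = c(3, 3, 3))
  expect_equal(utils::tail(top_variable_genes(flat, 10), 1), "g_const")
})

test_that("z-scoring standardises rows and flags degenerate ones", {
  m <- rbind(a = c(1, 2, 3), b = c(4, 4, 4))
  colnames(m) <- paste0("s", 1:3)
  expect_warning(z <- zscore_rows(m), "constant")
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(unname(z["b", ]), c(0, 0, 0))

  set.seed(12)
  big <- matrix(rnorm(40 * 6), nrow = 40,
                dimnames = list(sprintf("g%02d", 1:40), sprintf("s%d", 1:6)))
  z2 <- zscore_rows(big)
  expect_true(all(abs(rowMeans(z2)) <= 1e-12))
  expect_true(all(abs(apply(z2, 1, sd) - 1) <= 1e-12))
  # idempotence on standardised rows
  expect_equal(zscore_rows(z2), z2, tolerance = 1e-12)
})

test_that("sample clustering matches a naive complete-linkage oracle", {
  set.seed(5)
  m <- matrix(rnorm(10 * 5), nrow = 10,
              dimnames = list(paste0("g", 1:10), c("s3", "s1", "s4", "s2", "s5")))
  cl <- cluster_samples(m)
  oracle <- complete_linkage_oracle(m[, order(colnames(m))])
  expect_equal(cl$height, oracle$heights, tolerance = 1e-9)
  for (step in seq_along(oracle$partitions)) {
    k <- ncol(m) - step
    if (k < 1) break
    got <- canon_partition(stats::cutree(cl$hclust, k = k))
    want <- oracle$partitions[[step]]
    want <- want[order(vapply(want, `[[`, "", 1L))]
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("clustering is invariant to input column order; twins merge at 0", {
  set.seed(6)
  m <- matrix(rnorm(8 * 4), nrow = 8,
              dimnames = list(paste0("g", 1:8), c("a", "b", "c", "d")))
  m[, "d"] <- m[, "a"]  # identical samples
  cl <- cluster_samples(m)
  expect_equal(min(cl$height), 0)
  perm <- m[, c("c", "a", "d", "b")]
  cl2 <- cluster_samples(perm)
  expect_equal(cl2$merge, cl$merge)
  expect_equal(cl2$sample_order, cl$sample_order)
})

test_that("network is the induced interactome subgraph with co-citations", {
  scores <- c(G1 = 3, G2 = 2, G3 = 1)
  inter <- data.frame(gene_a = c("G1", "G2"), gene_b = c("G2", "G4"),
                      score = c(0.7, 0.9))
  cp <- jsonl_corpus(list(list(pmid = "1"), list(pmid = "2"), list(pmid = "3")))
  ann <- list(`1` = c("G1", "G2"), `2` = c("G1", "G2"), `3` = "G1")
  net <- build_gene_network(scores, inter, cp, ann)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$gene_a, "G1")
  expect_equal(net$edges$gene_b, "G2")
  expect_equal(net$edges$score, 0.7)
  expect_equal(net$edges$cocitation, 2L)
  # no overlap: isolated scored nodes
  lonely <- build_gene_network(c(A = 1), inter, cp, ann)
  expect_equal(nrow(lonely$edges), 0L)
  expect_equal(lonely$nodes$gene, "A")
})

test_that("edge set equals a naive endpoint filter on random fixtures", {
  set.seed(17)
  genes <- sprintf("G%02d", 1:12)
  scores <- stats::setNames(runif(8), sample(genes, 8))
  pairs <- t(combn(genes, 2))
  take <- sample(nrow(pairs), 30)
  inter <- data.frame(gene_a = pairs[take, 1], gene_b = pairs[take, 2],
                      score = runif(30))
  net <- build_gene_network(scores, inter)
  naive <- inter[inter$gene_a %in% names(scores) &
                 inter$gene_b %in% names(scores), ]
  naive_keys <- sort(paste(pmin(naive$gene_a, naive$gene_b),
                           pmax(naive$gene_a, naive$gene_b)))
  expect_equal(sort(paste(net$edges$gene_a, net$edges$gene_b)),
               unique(naive_keys))
  expect_true(all(net$edges$gene_a < net$edges$gene_b))  # no self, canonical
})

test_that("co-citation counting matches brute-force enumeration", {
  set.seed(23)
  genes <- sprintf("G%02d", 1:10)
  pmids <- as.character(1:40)
  ann <- lapply(pmids, function(p) sample(genes, sample(2:5, 1)))
  names(ann) <- pmids
  cp <- jsonl_corpus(lapply(pmids, function(p) list(pmid = p)))
  scores <- stats::setNames(rep(1, 10), genes)
  pairs <- t(combn(genes, 2))
  inter <- data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2], score = 0.5)
  net <- build_gene_network(scores, inter, cp, ann)
  cites <- stats::setNames(vapply(genes, function(g)
    sum(vapply(ann, function(s) g %in% s, TRUE)), 0L), genes)
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$gene_a[[i]]; b <- net$edges$gene_b[[i]]
    brute <- sum(vapply(ann, function(s) a %in% s && b %in% s, TRUE))
    expect_identical(net$edges$cocitation[[i]], brute)
    expect_lte(net$edges$cocitation[[i]], min(cites[[a]], cites[[b]]))
  }
})
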