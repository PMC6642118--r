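# hand-derived closed forms on the 5-node toy tree (A=A01, B=A01.111,
# C=A01.111.222, D=A01.111.333, E=A01.444; max depth 3)
test_that("all six measures reproduce the toy-tree closed forms", {
  tr <- toy_tree()
  unit_ic <- ic_cumulative(tr, stats::setNames(rep(1, 5),
                                               names(tr$descriptors)))
  cfg <- similarity_config(ic_table = unit_ic)
  expect_equal(sim_shortest_path(tr, "DC", "DD"), 1 - 2 / 6, tolerance = 1e-12)
  expect_equal(sim_shortest_path(tr, "DC", "DE"), 0.5, tolerance = 1e-12)
  expect_equal(sim_wu_palmer(tr, "DC", "DD"), 2 / 3, tolerance = 1e-12)
  expect_equal(sim_leacock_chodorow(tr, "DC", "DD"), -log(3 / 6) / log(6),
               tolerance = 1e-12)
  expect_equal(sim_li(tr, "DC", "DD"), exp(-0.4) * tanh(1.2), tolerance = 1e-12)
  expect_equal(sim_lord(tr, "DC", "DD", cfg), log(5 / 3) / log(5),
               tolerance = 1e-12)
  expect_equal(sim_weighted_link(tr, "DC", "DD"), 1 - 0.25 / 1.75,
               tolerance = 1e-12)
  # four-decimal printed forms
  expect_equal(round(sim_leacock_chodorow(tr, "DC", "DD"), 4), 0.3869)
  expect_equal(round(sim_li(tr, "DC", "DD"), 4), 0.5588)
  expect_equal(round(sim_lord(tr, "DC", "DD", cfg), 4), 0.3174)
  expect_equal(round(sim_weighted_link(tr, "DC", "DD"), 4), 0.8571)
})

test_that("identity values are as documented", {
  tr <- toy_tree()
  cfg <- similarity_config(ic_table = ic_cumulative(
    tr, stats::setNames(rep(1, 5), names(tr$descriptors))))
  expect_equal(sim_shortest_path(tr, "DC", "DC"), 1)
  expect_equal(sim_wu_palmer(tr, "DC", "DC"), 1)
  expect_equal(sim_leacock_chodorow(tr, "DC", "DC"), 1)
  expect_equal(sim_weighted_link(tr, "DC", "DC"), 1)
  expect_equal(sim_lord(tr, "DC", "DC", cfg), 1)
  # Li's identity saturates below 1 by construction
  expect_equal(sim_li(tr, "DC", "DC"), tanh(0.6 * 3), tolerance = 1e-12)
  expect_lt(sim_li(tr, "DC", "DC"), 1)
})

test_that("disjoint categories score zero where the lca is the root", {
  tf <- withr::local_tempfile()
  writeLines(c("P\tp\tA01", "Q\tq\tB02", "P2\tp2\tA01.111", "Q2\tq2\tB02.200"), tf)
  tr <- parse_mesh(tf, "tsv")
  cfg <- similarity_config(ic_table = ic_cumulative(
    tr, stats::setNames(rep(1, 4), names(tr$descriptors))))
  expect_equal(sim_wu_palmer(tr, "P2", "Q2"), 0)
  expect_equal(sim_li(tr, "P2", "Q2"), 0)       # tanh(0)
  expect_equal(sim_lord(tr, "P2", "Q2", cfg), 0)
})

test_that("every measure is symmetric and bounded in [0,1] on random trees", {
  for (seed in 1:2) {
    tr <- random_tree(25L, max_depth = 4L, seed = seed, p_multi = 0.2)
    uis <- names(tr$descriptors)
    cfg <- similarity_config(ic_table = ic_cumulative(
      tr, stats::setNames(seq_along(uis), uis)))
    for (m in c("shortest_path", "weighted_link", "wu_palmer",
                "leacock_chodorow", "li", "lord")) {
      for (a in uis[seq(1, 25, by = 4)])
        for (b in uis[seq(2, 25, by = 5)]) {
          s <- mesh_similarity(tr, a, b, m, cfg)
          expect_gte(s, 0); expect_lte(s, 1)
          expect_equal(s, mesh_similarity(tr, b, a, m, cfg), tolerance = 1e-12)
        }
    }
  }
})

test_that("path-based measures decay with distance on a chain", {
  tf <- withr::local_tempfile()
  codes <- vapply(1:6, function(k)
    paste(c("A01", rep("111", k - 1L)), collapse = "."), "")
  writeLines(sprintf("C%d\tc%d\t%s", 1:6, 1:6, codes), tf)
  tr <- parse_mesh(tf, "tsv")
  for (m in c("shortest_path", "weighted_link", "leacock_chodorow")) {
    s <- vapply(2:6, function(k)
      mesh_similarity(tr, "C1", paste0("C", k), m), 0)
    expect_true(all(diff(s) < 1e-12))  # non-increasing in path length
  }
  # deeper sibling pairs outscore shallower ones under weighted-link
  tf2 <- withr::local_tempfile()
  writeLines(c("R\tr\tA01", "S1\ts1\tA01.100", "S2\ts2\tA01.200",
               "M\tm\tA01.100.110", "D1\td1\tA01.100.110.111",
               "D2\td2\tA01.100.110.222"), tf2)
  tr2 <- parse_mesh(tf2, "tsv")
  expect_gt(sim_weighted_link(tr2, "D1", "D2"),
            sim_weighted_link(tr2, "S1", "S2"))
})

test_that("Lord similarity is invariant to count rescaling", {
  tr <- toy_tree()
  counts <- stats::setNames(c(2, 1, 4, 3, 5), names(tr$descriptors))
  s1 <- sim_lord(tr, "DC", "DD",
                 similarity_config(ic_table = ic_cumulative(tr, counts)))
  s2 <- sim_lord(tr, "DC", "DD",
                 similarity_config(ic_table = ic_cumulative(tr, counts * 37.5)))
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("set similarity is the best-match average", {
  tr <- toy_tree()
  expect_equal(set_similarity(tr, c("DC", "DD"), c("DC", "DD")), 1)
  expect_equal(set_similarity(tr, "DC", "DD"),
               sim_shortest_path(tr, "DC", "DD"))
  # exhaustive double-loop oracle on 3-vs-4 sets
  A <- c("DB", "DC", "DE"); B <- c("DA", "DB", "DD", "DE")
  S <- outer(A, B, Vectorize(function(a, b) sim_shortest_path(tr, a, b)))
  want <- (sum(apply(S, 1, max)) + sum(apply(S, 2, max))) / (length(A) + length(B))
  expect_equal(set_similarity(tr, A, B), want, tolerance = 1e-12)
  # unresolvable terms drop with a report; empty set errors
  expect_warning(s <- set_similarity(tr, c("DC", "bogus"), "DD"), "excluded")
  expect_equal(s, sim_shortest_path(tr, "DC", "DD"))
  expect_error(suppressWarnings(set_similarity(tr, "bogus", "DD")),
               "empty after resolution")
})

test_that("the 0.5 significance threshold is inclusive", {
  expect_true(significance_flag(0.84))
  expect_true(significance_flag(0.5))
  expect_false(significance_flag(0.49))
  expect_error(significance_flag(1.2), "\\[0, 1\\]")
  expect_error(significance_flag(-0.1), "\\[0, 1\\]")
})
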