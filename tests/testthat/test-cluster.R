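test_that("p-distances follow the mismatch definition", {
  msa <- sreb_msa(c(a = "AAAA", b = "AAAT", c = "AAAA"))
  d <- pairwise_distances(msa)
  expect_equal(d$d["a", "b"], 0.25)
  expect_equal(d$d["a", "c"], 0)
  expect_true(isSymmetric(d$d))
  expect_true(all(diag(d$d) == 0))
  ## gap columns are excluded pairwise
  msa2 <- sreb_msa(c(a = "AA-A", b = "AAT-"))
  expect_equal(pairwise_distances(msa2)$d["a", "b"], 0)
  ## no comparable columns: distance 1 with a warning
  msa3 <- sreb_msa(c(a = "A--", b = "-AA"))
  expect_warning(d3 <- pairwise_distances(msa3), "no comparable")
  expect_equal(d3$d["a", "b"], 1)
})

test_that("neighbor-joining is exact on additive tree metrics", {
  ## 3 taxa: any metric is additive and NJ reproduces it exactly
  m <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(m)
  expect_equal(unname(ape::cophenetic.phylo(tr)[c("a", "b", "c"), c("a", "b", "c")]),
               unname(m), tolerance = 1e-12)
  ## 4-taxon additive metrics: the recovered split matches the four-point
  ## oracle over all three possible quartets
  set.seed(7)
  for (rep in 1:20) {
    tr0 <- ape::rtree(4, tip.label = c("t1", "t2", "t3", "t4"))
    tr0$edge.length <- stats::runif(nrow(tr0$edge), 0.05, 1)
    d <- ape::cophenetic.phylo(tr0)[c("t1", "t2", "t3", "t4"),
                                    c("t1", "t2", "t3", "t4")]
    expect_identical(tree_quartet(nj_tree(d)), oracle_quartet(d))
    expect_identical(oracle_quartet(d), tree_quartet(tr0))
  }
  expect_error(nj_tree(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))),
               "at least 3")
  ## negative branch lengths are clamped
  fam <- simulate_family(small_config(seed = 61))
  tr2 <- nj_tree(pairwise_distances(family_msa(fam)))
  expect_true(all(tr2$edge.length >= 0))
})

test_that("well-separated synthetic clusters are monophyletic in the NJ tree", {
  fam <- simulate_family(small_config(seed = 62))
  msa <- family_msa(fam, drop_outgroup = FALSE)
  tr <- nj_tree(pairwise_distances(msa))
  og <- msa$ids[msa$clusters == "sreb_like"]
  tr <- ape::root(tr, outgroup = og, resolve.root = TRUE)
  for (cl in c("SREB1", "SREB2", "SREB3A", "SREB3B")) {
    tips <- msa$ids[msa$clusters == cl]
    expect_true(ape::is.monophyletic(tr, tips))
  }
})

test_that("bootstrap assignment is deterministic and hint-consistent", {
  fam <- simulate_family(small_config(seed = 63))
  g <- fam$genes[is.na(fam$genes$qc), ]
  msa <- align_or_import(stats::setNames(g$protein, g$gene_id), "import",
                         clusters = stats::setNames(g$cluster_hint, g$gene_id))
  hints <- stats::setNames(g$cluster_hint, g$gene_id)
  og <- g$gene_id[g$cluster_hint == "sreb_like"]
  b1 <- bootstrap_clusters(msa, hints, n_boot = 40L, seed = 5, outgroup = og,
                           candidate_clusters = c("SREB1", "SREB2", "SREB3A", "SREB3B"))
  b2 <- bootstrap_clusters(msa, hints, n_boot = 40L, seed = 5, outgroup = og,
                           candidate_clusters = c("SREB1", "SREB2", "SREB3A", "SREB3B"))
  expect_identical(b1$assignments, b2$assignments)
  expect_equal(unname(b1$support), rep(1, 4))
  ## outgroup-like sequences stay unassigned
  expect_true(all(b1$assignments$assigned[b1$assignments$gene_id %in% og] ==
                    "UNASSIGNED"))
  ## every other sequence keeps its hint at full support
  rest <- b1$assignments[!b1$assignments$gene_id %in% og, ]
  expect_identical(rest$assigned, rest$cluster_hint)
})

test_that("zero-substitution clusters get full support", {
  cfg <- small_config(seed = 64,
                      subst_prob = c(SREB1 = 0, SREB2 = 0, SREB3A = 0, SREB3B = 0))
  fam <- simulate_family(cfg)
  g <- fam$genes
  msa <- align_or_import(stats::setNames(g$protein, g$gene_id), "import",
                         clusters = stats::setNames(g$cluster_hint, g$gene_id))
  og <- g$gene_id[g$cluster_hint == "sreb_like"]
  b <- bootstrap_clusters(msa, stats::setNames(g$cluster_hint, g$gene_id),
                          n_boot = 30L, seed = 2, outgroup = og,
                          candidate_clusters = c("SREB1", "SREB2", "SREB3A", "SREB3B"))
  expect_equal(unname(b$support), rep(1, 4))
})

test_that("cluster recovery is perfect across seeds on separated data", {
  skip_if_not_installed("mclust")
  ok <- 0L; n_seed <- 5L
  for (seed in seq_len(n_seed)) {
    fam <- simulate_family(small_config(seed = 100 + seed))
    g <- fam$genes[is.na(fam$genes$qc) & fam$genes$cluster_hint != "sreb_like", ]
    msa <- align_or_import(stats::setNames(g$protein, g$gene_id), "import",
                           clusters = stats::setNames(g$cluster_hint, g$gene_id))
    b <- bootstrap_clusters(msa, stats::setNames(g$cluster_hint, g$gene_id),
                            n_boot = 50L, seed = seed,
                            candidate_clusters = c("SREB1", "SREB2", "SREB3A", "SREB3B"))
    ari <- mclust::adjustedRandIndex(b$assignments$assigned, g$cluster_hint)
    if (ari == 1) ok <- ok + 1L
  }
  expect_equal(ok, n_seed)
})
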