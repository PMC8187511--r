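test_that("minimum conservation percentage matches the printed thresholds", {
  ## the four cluster sizes of the final comparative dataset
  expect_equal(min_conservation_pct(75), 96.0)
  expect_equal(min_conservation_pct(80), 96.3)
  expect_equal(min_conservation_pct(69), 95.7)
  expect_equal(min_conservation_pct(54), 94.4)
  ## boundary arithmetic and error path
  expect_equal(min_conservation_pct(4, 3), 25.0)
  expect_error(min_conservation_pct(3, 3), "exceed")
})

test_that("column profiles count gaps as divergent and break ties alphabetically", {
  ## 43-member cluster: A x40, T x2, one gap -> modal A, 3 divergent
  rows <- c(rep("A", 40), "T", "T", "-")
  ids <- sprintf("g%02d", seq_along(rows))
  msa <- sreb_msa(stats::setNames(rows, ids),
                  clusters = stats::setNames(rep("C1", length(rows)), ids),
                  reference_id = "g01")
  prof <- profile_columns(msa)
  c1 <- prof[prof$cluster == "C1", ]
  expect_equal(c1$modal, "A")
  expect_equal(c1$divergent_count, 3L)
  expect_true(c1$conserved)
  ## gap-ignoring policy drops the gap from the denominator
  ig <- profile_columns(msa, gap_policy = "ignore")
  expect_equal(ig$divergent_count[ig$cluster == "C1"], 2L)
  ## monomorphic column
  msa2 <- sreb_msa(stats::setNames(rep("W", 5), paste0("s", 1:5)),
                   clusters = stats::setNames(rep("C1", 5), paste0("s", 1:5)))
  p2 <- profile_columns(msa2)
  expect_equal(p2$divergent_count[p2$cluster == "C1"], 0L)
  expect_equal(p2$conservation[p2$cluster == "C1"], 1.0)
  ## alphabetical tie-break: equal A and C counts -> A
  msa3 <- sreb_msa(stats::setNames(c("C", "A", "C", "A"), paste0("t", 1:4)),
                   clusters = stats::setNames(rep("C1", 4), paste0("t", 1:4)))
  expect_equal(profile_columns(msa3)$modal[1], "A")
})

test_that("planted SREB3B-specific sites are recovered exactly", {
  fam <- simulate_family(small_config(seed = 41))
  msa <- family_msa(fam)
  scr <- screen_genes(fam$genes[fam$genes$gene_id %in% msa$ids, ])
  msa <- mask_nterminal(msa, scr)
  prof <- profile_columns(msa)
  sites <- find_cluster_specific_sites(prof, "SREB3B",
                                       c("SREB1", "SREB2", "SREB3A"))
  expect_identical(sites$ref_position, fam$truth$specific_sites$SREB3B)
  expect_identical(unique(sites$consensus_target),
                   unique(vapply(fam$truth$specific_residues, `[[`, "", "target")[
                     as.character(sites$ref_position)]))
  ## no planted sites -> empty result
  cfg0 <- small_config(seed = 42, n_specific_sites = c(SREB3B = 0L))
  fam0 <- simulate_family(cfg0)
  msa0 <- family_msa(fam0)
  scr0 <- screen_genes(fam0$genes[fam0$genes$gene_id %in% msa0$ids, ])
  msa0 <- mask_nterminal(msa0, scr0)
  sites0 <- find_cluster_specific_sites(profile_columns(msa0), "SREB3B",
                                        c("SREB1", "SREB2", "SREB3A"))
  expect_equal(nrow(sites0), 0L)
})

test_that("sites where background clusters disagree are excluded", {
  ## construct a column where each background is conserved but they do not
  ## share a residue: rule (a) must reject it in strict mode
  ids <- sprintf("s%02d", 1:8)
  seqs <- c("AK", "AK", "AR", "AR", "AD", "AD", "AW", "AW")
  clusters <- rep(c("B1", "B2", "B3", "TG"), each = 2)
  msa <- sreb_msa(stats::setNames(seqs, ids),
                  clusters = stats::setNames(clusters, ids),
                  reference_id = "s01")
  prof <- profile_columns(msa, max_divergent = 0L)
  strict <- find_cluster_specific_sites(prof, "TG", c("B1", "B2", "B3"))
  expect_false(2L %in% strict$ref_position)
  relaxed <- find_cluster_specific_sites(prof, "TG", c("B1", "B2", "B3"),
                                         require_shared_background = FALSE)
  expect_true(2L %in% relaxed$ref_position)
})

test_that("profiles and specific sites agree with a brute-force oracle", {
  for (seed in 1:8) {
    msa <- random_msa(seed, n_rows = 24L, n_cols = 80L)
    prof <- profile_columns(msa)
    m <- do.call(rbind, strsplit(unname(msa$seqs), ""))
    agree <- TRUE
    for (cl in c("C1", "C3")) {
      rows <- which(msa$clusters == cl)
      sub <- prof[prof$cluster == cl, ]
      for (j in c(1L, 17L, 50L, 80L)) {
        o <- oracle_column(m[rows, j])
        if (!identical(sub$modal[j], o$modal) ||
            sub$divergent_count[j] != o$divergent_count ||
            sub$conserved[j] != o$conserved) agree <- FALSE
      }
    }
    expect_true(agree, label = paste("profile oracle, seed", seed))
    mine <- find_cluster_specific_sites(prof, "C4", c("C1", "C2", "C3"))
    expect_identical(mine$ref_position,
                     oracle_specific_sites(msa, "C4", c("C1", "C2", "C3")))
  }
})

test_that("specific-site detection is invariant under row permutation", {
  fam <- simulate_family(small_config(seed = 44))
  msa <- family_msa(fam)
  set.seed(99)
  perm <- sample(seq_along(msa$ids))
  msa_p <- sreb_msa(msa$seqs[perm], msa$clusters[perm], msa$reference_id)
  s1 <- find_cluster_specific_sites(profile_columns(msa), "SREB3B",
                                    c("SREB1", "SREB2", "SREB3A"))
  s2 <- find_cluster_specific_sites(profile_columns(msa_p), "SREB3B",
                                    c("SREB1", "SREB2", "SREB3A"))
  expect_identical(s1$ref_position, s2$ref_position)
  expect_identical(s1$consensus_target, s2$consensus_target)
})

test_that("masked N-terminal columns never yield reported sites", {
  fam <- simulate_family(small_config(seed = 45))
  msa <- family_msa(fam)
  scr <- screen_genes(fam$genes[fam$genes$gene_id %in% msa$ids, ])
  msa <- mask_nterminal(msa, scr)
  prof <- profile_columns(msa)
  sites <- find_cluster_specific_sites(prof, "SREB3B",
                                       c("SREB1", "SREB2", "SREB3A"))
  tm1 <- scr$tm1_start[scr$gene_id == msa$reference_id]
  expect_true(all(sites$ref_position >= tm1))
})
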