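test_that("identical configurations give byte-identical outputs", {
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  fam1 <- simulate_family(small_config(seed = 11))
  fam2 <- simulate_family(small_config(seed = 11))
  write_family_fasta(fam1, f1); write_family_fasta(fam2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(fam1$genes, fam2$genes)
  g1 <- simulate_genomes(small_config(seed = 11), fam1)
  g2 <- simulate_genomes(small_config(seed = 11), fam2)
  t1 <- tempfile(); t2 <- tempfile()
  write_genomes_tsv(g1, t1); write_genomes_tsv(g2, t2)
  expect_identical(readLines(t1), readLines(t2))
  ct1 <- simulate_ct(small_config(seed = 11))
  ct2 <- simulate_ct(small_config(seed = 11))
  expect_identical(ct1$ct_table, ct2$ct_table)
})

test_that("zero substitution probability gives identical sequences within clusters", {
  cfg <- small_config(seed = 3,
                      subst_prob = c(SREB1 = 0, SREB2 = 0, SREB3A = 0, SREB3B = 0))
  fam <- simulate_family(cfg)
  for (cl in cfg$clusters) {
    seqs <- fam$genes$protein[fam$genes$cluster_hint == cl]
    expect_length(unique(seqs), 1L)
  }
  ## no divergent residues at any column
  msa <- family_msa(fam)
  prof <- profile_columns(msa)
  per_cluster <- prof[prof$cluster != "(pooled)", ]
  expect_true(all(per_cluster$divergent_count == 0L))
})

test_that("higher substitution probability lowers within-cluster identity", {
  ## conservation ordering, allowing one sampling violation in ten seeds
  violations <- 0L
  for (seed in 1:10) {
    fam <- simulate_family(small_config(seed = seed))
    msa <- family_msa(fam)
    d <- pairwise_distances(msa)
    mean_within <- function(cl) {
      ids <- msa$ids[!is.na(msa$clusters) & msa$clusters == cl]
      mean(d$d[ids, ids][upper.tri(diag(length(ids)))])
    }
    ## default rates order: SREB2 < SREB1 < SREB3A < SREB3B
    w <- vapply(c("SREB2", "SREB1", "SREB3A", "SREB3B"), mean_within, 0)
    if (is.unsorted(w)) violations <- violations + 1L
  }
  expect_lte(violations, 1L)
})

test_that("planted cluster-specific sites are monomorphic and diagnostic", {
  fam <- simulate_family(small_config(seed = 5))
  g <- fam$genes[fam$genes$cluster_hint != "sreb_like", ]
  sites <- fam$truth$specific_sites$SREB3B
  expect_length(sites, 8L)
  for (pos in sites) {
    res <- substr(g$protein, pos, pos)
    target <- unique(res[g$cluster_hint == "SREB3B"])
    other <- unique(res[g$cluster_hint != "SREB3B"])
    expect_length(target, 1L)
    expect_length(other, 1L)
    expect_false(target == other)
  }
})

test_that("loss events remove family genes but flanking genes survive", {
  cfg <- sim_config(seed = 2)
  fam <- simulate_family(cfg)
  lost <- fam$truth$losses
  cypr <- lost$species[lost$cluster == "SREB3A" & lost$mode == "gene_loss"]
  expect_length(cypr, 8L)
  expect_false(any(fam$genes$species %in% cypr &
                     fam$genes$cluster_hint == "SREB3A"))
  gen <- simulate_genomes(cfg, fam)
  for (sp in cypr) {
    syms <- gen[[sp]]$symbol
    expect_true(all(c("foxp3b", "suv39h1") %in% syms))
    expect_false("sreb3a" %in% syms)
  }
  ## assembly gap drops the downstream flanker too
  gap_sp <- lost$species[lost$mode == "assembly_gap"]
  for (sp in gap_sp) {
    syms <- gen[[sp]]$symbol
    expect_false("wdr13" %in% syms)
    expect_false("sreb3b" %in% syms)
    expect_true(all(c("tspy", "ppp1r3f") %in% syms))
  }
})

test_that("duplication events add a second copy beside the original", {
  cfg <- sim_config(seed = 4)
  fam <- simulate_family(cfg)
  dups <- grep("_2$", fam$genes$gene_id, value = TRUE)
  expect_length(dups, 2L)
  expect_true(all(fam$genes$cluster_hint[fam$genes$gene_id %in% dups] == "SREB2"))
  gen <- simulate_genomes(cfg, fam)
  sp <- sub("_sreb2_2$", "", dups[1])
  expect_true("sreb2b" %in% gen[[sp]]$symbol)
})

test_that("simulated Ct obeys the standard-curve closed forms", {
  expect_equal(round(efficiency_to_slope(1.0), 4), -3.3219)
  cfg <- small_config(seed = 9)
  cfg$qpcr$ct_sd <- 0
  cfg$qpcr$efficiency[] <- 1.0
  cfg$qpcr$planted_fold_changes$smim20 <- c(TS = 1, OVV = 8)
  sim <- simulate_ct(cfg)
  ct <- sim$ct_table[sim$ct_table$gene == "smim20", ]
  d_ct <- mean(ct$ct[ct$group == "TS"]) - mean(ct$ct[ct$group == "OVV"])
  expect_equal(d_ct, 3, tolerance = 1e-9)     # log2(8) cycles
  ## dilution series spans the configured points, noiseless and exact
  cur <- fit_standard_curve(sim$curves_input[sim$curves_input$gene == "smim20", ])
  expect_gte(nrow(cur$points), 4L)
  expect_equal(cur$efficiency, 1.0, tolerance = 1e-9)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(subst_prob = c(SREB1 = 1.2)), "subst_prob|\\[0")
  expect_error(sim_config(loss_events = list(
    list(cluster = "SREB1", clade = "no_such_species", mode = "gene_loss"))),
    "clade not found")
  bad_qpcr <- default_qpcr_config()
  bad_qpcr$planted_fold_changes$sreb1["TS"] <- 2
  expect_error(sim_config(qpcr = bad_qpcr), "calibrator")
  bad_qpcr2 <- default_qpcr_config()
  bad_qpcr2$efficiency["sreb1"] <- 0.5
  expect_error(sim_config(qpcr = bad_qpcr2), "efficienc")
  cfg <- small_config()
  cfg$qpcr$base_quantity["sreb1"] <- -1
  expect_error(simulate_ct(cfg), "non-positive")
})
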