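## shared fixtures and independent oracles for the test suite

## a small four-cluster world: 4 clades x 4 species, one outgroup sequence
small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, group_names = paste0("clade", 1:4), n_per_group = 4L,
             n_outgroups = 1L, ...)
}

## import-mode MSA straight from a simulated family, using truth labels;
## drops qc failures and outgroup-like rows unless asked otherwise
family_msa <- function(fam, drop_qc = TRUE, drop_outgroup = TRUE,
                       reference_id = NULL) {
  g <- fam$genes
  keep <- rep(TRUE, nrow(g))
  if (drop_qc) keep <- keep & is.na(g$qc)
  if (drop_outgroup) keep <- keep & g$cluster_hint != "sreb_like"
  g <- g[keep, , drop = FALSE]
  if (is.null(reference_id)) {
    ref_candidates <- g$gene_id[g$cluster_hint == "SREB3A"]
    reference_id <- if (length(ref_candidates)) ref_candidates[1] else g$gene_id[1]
  }
  align_or_import(stats::setNames(g$protein, g$gene_id), "import",
                  clusters = stats::setNames(g$cluster_hint, g$gene_id),
                  reference_id = reference_id)
}

## literal brute-force conservation profile: one column, one cluster
oracle_column <- function(chars, max_divergent = 3L,
                          gap_policy = "divergent") {
  res <- chars[chars != "-"]
  n_gap <- sum(chars == "-")
  if (!length(res)) {
    modal <- NA_character_; modal_count <- 0L
  } else {
    tb <- sort(table(res))
    best <- max(tb)
    modal <- sort(names(tb)[tb == best])[1]     # alphabetical tie-break
    modal_count <- as.integer(best)
  }
  denom <- if (gap_policy == "divergent") length(chars) else length(res)
  divergent <- denom - modal_count
  list(modal = modal, modal_count = modal_count,
       divergent_count = divergent,
       conserved = divergent <= max_divergent,
       conservation = if (denom > 0) modal_count / denom else NA_real_)
}

## literal implementation of the cluster-specific-site rules (a)-(c)
oracle_specific_sites <- function(msa, target, background,
                                  max_divergent = 3L) {
  m <- do.call(rbind, strsplit(unname(msa$seqs), ""))
  rownames(m) <- msa$ids
  rp <- srebscan::ref_positions(msa)
  hits <- integer()
  for (j in seq_len(ncol(m))) {
    if (msa$masked[j] || is.na(rp[j])) next
    bg_modal <- character(); ok <- TRUE
    for (cl in background) {
      rows <- which(!is.na(msa$clusters) & msa$clusters == cl)
      o <- oracle_column(m[rows, j], max_divergent)
      if (!o$conserved || is.na(o$modal)) { ok <- FALSE; break }
      bg_modal <- c(bg_modal, o$modal)
    }
    if (!ok || length(unique(bg_modal)) != 1L) next
    rows <- which(!is.na(msa$clusters) & msa$clusters == target)
    o <- oracle_column(m[rows, j], max_divergent)
    if (!o$conserved || is.na(o$modal)) next
    if (o$modal != bg_modal[1]) hits <- c(hits, rp[j])
  }
  sort(hits)
}

## random labelled alignment (possibly gappy) for oracle-equivalence tests
random_msa <- function(seed, n_rows = 30L, n_cols = 120L, n_clusters = 4L,
                       gap_rate = 0.05) {
  set.seed(seed)
  alphabet <- c("A", "C", "D", "E", "K", "R", "S", "T")
  m <- matrix(sample(alphabet, n_rows * n_cols, replace = TRUE),
              n_rows, n_cols)
  m[stats::runif(length(m)) < gap_rate] <- "-"
  ids <- sprintf("s%02d", seq_len(n_rows))
  rownames(m) <- ids
  ## reference must be ungapped nowhere? gaps allowed; keep row 1 gap-free
  m[1, m[1, ] == "-"] <- "A"
  clusters <- stats::setNames(
    paste0("C", rep_len(seq_len(n_clusters), n_rows)), ids)
  sreb_msa(stats::setNames(apply(m, 1, paste, collapse = ""), ids),
           clusters = clusters, reference_id = ids[1])
}

## the three possible unrooted quartet splits of four taxa
oracle_quartet <- function(d) {
  ## four-point condition: the true split pairs the two sides with the
  ## smallest sum of within-pair distances
  taxa <- rownames(d)
  splits <- list(c(1, 2), c(1, 3), c(1, 4))
  sums <- vapply(splits, function(p) {
    q <- setdiff(1:4, p)
    d[p[1], p[2]] + d[q[1], q[2]]
  }, 0)
  p <- splits[[which.min(sums)]]
  side <- taxa[p]
  first <- sort(taxa)[1]
  if (!first %in% side) side <- setdiff(taxa, side)
  sort(side)
}

## unrooted split of a 4-taxon tree, normalized to the side holding the
## alphabetically first taxon
tree_quartet <- function(tr) {
  u <- ape::unroot(tr)
  pp <- ape::prop.part(u)
  labels <- attr(pp, "labels")
  sizes <- lengths(pp)
  inner <- pp[[which(sizes == 2L)[1]]]
  side <- labels[inner]
  first <- sort(labels)[1]
  if (!first %in% side) side <- setdiff(labels, side)
  sort(side)
}

## lazily computed, cached heavy fixtures (built once per test run)
.fixture_cache <- new.env(parent = emptyenv())
default_family_screened <- function(seed = 1L) {
  key <- paste0("fam", seed)
  if (is.null(.fixture_cache[[key]])) {
    fam <- simulate_family(sim_config(seed = seed))
    .fixture_cache[[key]] <- list(fam = fam, scr = screen_genes(fam$genes))
  }
  .fixture_cache[[key]]
}
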