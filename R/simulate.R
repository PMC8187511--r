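## ---- synthetic sequence-family generator --------------------------------

## residue pool for a position, given the architecture region class
.region_pool <- function(region) if (region == "tm") .tm_pool else .loop_pool

## planted residues at a cluster-specific site depend on where it falls:
## inside a transmembrane run the background/target pair is hydrophobic
## (V -> F, mirroring a small-to-large side-chain shift), in the C-terminal
## tail C -> Y, elsewhere N -> K
.specific_residues <- function(pos, arch) {
  tail_start <- arch$tm_segments[nrow(arch$tm_segments), "end"] + 1L
  if (arch$region[pos] == "tm") c(background = "V", target = "F")
  else if (pos >= tail_start) c(background = "C", target = "Y")
  else c(background = "N", target = "K")
}

## root values planted at the three canonical class-A GPCR motifs:
## DRY -> TRY (the family-wide D-to-T replacement), CWxP -> LWAP
## (C-to-L outside SREB1; SREB1 ancestors revert to C), NPxxY -> NPSAC
## (Y-to-C; derived-clade SREB1 tips carry S instead)
.motif_root_values <- function(anchors) {
  v <- character()
  v[as.character(anchors["DRY"] + 0:2)] <- c("T", "R", "Y")
  v[as.character(anchors["CWxP"] + 0:3)] <- c("L", "W", "A", "P")
  v[as.character(anchors["NPxxY"] + 0:4)] <- c("N", "P", "S", "A", "C")
  v
}

.resolve_specific_positions <- function(config) {
  arch <- config$architecture
  out <- list()
  motif_pos <- as.integer(names(.motif_root_values(config$motif_anchors)))
  pool <- .default_specific_positions
  extra <- setdiff(which(arch$region == "loop"), c(motif_pos, pool))
  extra <- extra[extra > arch$n_term]
  for (cl in names(config$n_specific_sites)) {
    n <- config$n_specific_sites[[cl]]
    if (n == 0) next
    pos <- c(pool, extra)[seq_len(n)]
    if (any(pos > arch$length))
      stop("planted sites exceeding protein length")
    out[[cl]] <- sort(as.integer(pos))
  }
  out
}

## mutate `seq` (character vector) at `mutable` sites with per-site
## probability p_eff, drawing replacements from the region-class pool
.mutate_sites <- function(seq, mutable, p_eff, region) {
  if (p_eff <= 0 || length(mutable) == 0L) return(seq)
  hits <- mutable[stats::runif(length(mutable)) < p_eff]
  for (i in hits) {
    pool <- setdiff(.region_pool(region[i]), seq[i])
    seq[i] <- pool[sample.int(length(pool), 1L)]
  }
  seq
}

## evolve an ancestral sequence along an ultrametric tree; returns a named
## list of tip sequences (character vectors)
.evolve_tree <- function(tree, ancestor, mutable, p, region) {
  tree <- stats::reorder(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  seqs <- vector("list", n_tip + tree$Nnode)
  root <- n_tip + 1L
  seqs[[root]] <- ancestor
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    ## the cluster ancestor is placed at the first split: the two root
    ## edges carry no change, so no single pair of deep mutations can make
    ## a whole cluster monomorphic for a non-ancestral residue (which
    ## would mimic a planted cluster-specific site)
    b <- if (parent == root) 0 else tree$edge.length[e]
    p_eff <- 1 - (1 - p)^b
    seqs[[child]] <- .mutate_sites(seqs[[parent]], mutable, p_eff, region)
  }
  stats::setNames(seqs[seq_len(n_tip)], tree$tip.label)
}

## reverse-translate with the fixed codon table; adds a stop codon and short
## untranslated flanks free of ATG so the planted ORF is the longest one
.utr5 <- "CCTTCCTTCCTT"
.utr3 <- "CCTTCCTTCCTT"

reverse_translate <- function(aa) {
  codons <- .codon_table[strsplit(aa, "")[[1]]]
  if (anyNA(codons)) stop("cannot reverse-translate residue(s): ",
                          paste(unique(strsplit(aa, "")[[1]][is.na(codons)]), collapse = ""))
  paste0(.utr5, paste(codons, collapse = ""), "TAA", .utr3)
}

#' Simulate a multi-species SREB-like gene family with planted ground truth
#'
#' Generates one nucleotide gene per species and paralog cluster (minus
#' configured losses, plus configured duplications), evolved i.i.d. per site
#' along the species tree under a uniform-replacement model within
#' hydrophobic (transmembrane) or hydrophilic (loop) residue pools. Planted
#' cluster-specific sites and canonical-motif positions are held immutable;
#' between-cluster separation additionally comes from a pool of diagnostic
#' sites at which exactly one pair of clusters differs, a pattern that can
#' never mimic a planted target-specific site. Configured quality-control
#' failures emit proteins with an aberrant transmembrane-run count or a
#' truncated reading frame.
#'
#' @param config a [sim_config()] object
#' @return list of class `sreb_family` with elements `genes` (data frame:
#'   gene_id, species, cluster_hint, qc, protein, sequence), `truth`
#'   (planted specific sites with residues, loss events, qc failures, qPCR
#'   fold changes), `tree` (the resolved species tree) and `config`
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  arch <- config$architecture
  with_seed(config$seed, {
    tree <- species_tree(config)
    for (ev in c(config$loss_events, config$duplication_events)) {
      if (length(ev$clade) > 1 &&
          !ape::is.monophyletic(tree, ev$clade))
        stop("clade not found in tree (not monophyletic): ",
             paste(ev$clade, collapse = ", "))
    }

    L <- arch$length
    motif_vals <- .motif_root_values(config$motif_anchors)
    motif_pos <- as.integer(names(motif_vals))
    specific <- .resolve_specific_positions(config)
    specific_pos <- sort(unique(unlist(specific, use.names = FALSE)))
    if (length(intersect(specific_pos, motif_pos)))
      stop("planted specific sites collide with motif anchors")

    ## family root backbone
    root <- character(L)
    for (i in seq_len(L)) {
      pool <- .region_pool(arch$region[i])
      root[i] <- pool[sample.int(length(pool), 1L)]
    }
    root[1L] <- "M"                    # initiator, immutable
    root[motif_pos] <- motif_vals[as.character(motif_pos)]
    site_res <- lapply(specific_pos, .specific_residues, arch = arch)
    names(site_res) <- as.character(specific_pos)
    for (p in specific_pos) root[p] <- site_res[[as.character(p)]]["background"]

    immutable <- sort(unique(c(1L, motif_pos, specific_pos)))
    mutable <- setdiff(seq_len(L), immutable)

    ## diagnostic divergence pool: each site separates exactly one cluster
    ## pair, so no site can be conserved-and-shared across three background
    ## clusters yet divergent in the fourth unless it was planted
    clusters <- config$clusters
    n_pool <- min(config$divergence_pool, length(mutable))
    pool_sites <- sort(sample(mutable, n_pool))
    pairs <- utils::combn(clusters, 2)
    pair_of_site <- ((seq_len(n_pool) - 1L) %% ncol(pairs)) + 1L

    ancestors <- stats::setNames(rep(list(root), length(clusters)), clusters)
    for (s in seq_len(n_pool)) {
      pos <- pool_sites[s]
      pool <- setdiff(.region_pool(arch$region[pos]), root[pos])
      res <- sample(pool, 2L)
      cl <- pairs[, pair_of_site[s]]
      ancestors[[cl[1]]][pos] <- res[1]
      ancestors[[cl[2]]][pos] <- res[2]
    }
    ## SREB1 retains the canonical cysteine at the CWxP anchor
    if ("SREB1" %in% clusters)
      ancestors[["SREB1"]][config$motif_anchors["CWxP"]] <- "C"
    for (cl in names(specific))
      ancestors[[cl]][specific[[cl]]] <-
        vapply(as.character(specific[[cl]]), function(p) site_res[[p]]["target"], "")

    ## evolve every cluster over the full species tree
    tips <- stats::setNames(vector("list", length(clusters)), clusters)
    for (cl in clusters)
      tips[[cl]] <- .evolve_tree(tree, ancestors[[cl]], mutable,
                                 config$subst_prob[[cl]], arch$region)

    ## assemble the gene table
    lost <- do.call(rbind, lapply(config$loss_events, function(ev)
      data.frame(species = ev$clade, cluster = ev$cluster, mode = ev$mode)))
    if (is.null(lost))
      lost <- data.frame(species = character(), cluster = character(),
                         mode = character())
    is_lost <- function(sp, cl)
      any(lost$species == sp & lost$cluster == cl)

    qc_of <- function(sp, cl) {
      for (qc in config$qc_failures)
        if (qc$species == sp && qc$cluster == cl) return(qc)
      NULL
    }

    derived_species <- species_names(config$derived_groups, config$n_per_group)

    rows <- list()
    species_order <- tree$tip.label
    for (cl in clusters) {
      for (sp in species_order) {
        if (is_lost(sp, cl)) next
        aa <- tips[[cl]][[sp]]
        if (cl == "SREB1") {
          if (sp %in% derived_species)
            aa[config$motif_anchors["NPxxY"] + 4L] <- "S"
          if (identical(sp, config$dry_exception))
            aa[config$motif_anchors["DRY"]] <- "D"
        }
        qc <- qc_of(sp, cl)
        copies <- list(aa)
        ids <- paste0(sp, "_", tolower(cl))
        for (dup in config$duplication_events) {
          if (dup$cluster == cl && sp %in% dup$clade) {
            extra <- .mutate_sites(aa, mutable,
                                   1 - (1 - config$subst_prob[[cl]])^0.1,
                                   arch$region)
            copies <- c(copies, list(extra))
            ids <- c(ids, paste0(sp, "_", tolower(cl), "_2"))
          }
        }
        for (k in seq_along(copies)) {
          aa_k <- copies[[k]]
          qc_tag <- NA_character_
          if (k == 1L && !is.null(qc)) {
            if (qc$failure == "tm_count") {
              qc_tag <- paste0("tm_count_", qc$k)
              aa_k <- .apply_tm_failure(aa_k, qc$k, arch)
            } else {
              qc_tag <- "truncated_orf"
              aa_k <- aa_k[seq_len(150L)]
            }
          }
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = ids[k], species = sp, cluster_hint = cl,
            qc = qc_tag, protein = paste(aa_k, collapse = ""),
            sequence = reverse_translate(paste(aa_k, collapse = "")),
            stringsAsFactors = FALSE)
        }
      }
    }

    ## divergent outgroup-like sequences (agnathan/shark analogues)
    og_names <- c("hagfish_like", "lamprey_like", "shark_like")
    if (config$n_outgroups > length(og_names))
      og_names <- c(og_names, sprintf("outgroup_%02d",
                                      seq_len(config$n_outgroups - 3L) + 3L))
    for (i in seq_len(config$n_outgroups)) {
      aa <- .mutate_sites(root, mutable, 0.45, arch$region)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = paste0(og_names[i], "_sreb_like"), species = og_names[i],
        cluster_hint = "sreb_like", qc = NA_character_,
        protein = paste(aa, collapse = ""),
        sequence = reverse_translate(paste(aa, collapse = "")),
        stringsAsFactors = FALSE)
    }

    genes <- do.call(rbind, rows)
    rownames(genes) <- NULL

    truth <- list(
      specific_sites = specific,
      specific_residues = site_res,
      losses = lost,
      qc_failures = config$qc_failures,
      fold_changes = config$qpcr$planted_fold_changes,
      dry_exception = config$dry_exception,
      motif_anchors = config$motif_anchors
    )
    structure(list(genes = genes, truth = truth, tree = tree,
                   config = config), class = "sreb_family")
  })
}

## rewrite a protein so the hydropathy screen sees k transmembrane runs
.apply_tm_failure <- function(aa, k, arch) {
  segs <- arch$tm_segments
  n_tm <- nrow(segs)
  if (k < n_tm) {
    for (i in (k + 1L):n_tm) {
      idx <- segs[i, 1]:segs[i, 2]
      aa[idx] <- .loop_pool[sample.int(length(.loop_pool), length(idx),
                                       replace = TRUE)]
    }
  } else if (k > n_tm) {
    ## plant an additional hydrophobic run in the C-terminal tail, clear of
    ## the NPxxY anchor and of TM7's detected span
    extra <- 350:370
    if (max(extra) > arch$length) stop("architecture too short for an extra run")
    aa[extra] <- .tm_pool[sample.int(length(.tm_pool), length(extra),
                                     replace = TRUE)]
  }
  aa
}
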