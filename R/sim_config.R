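## ---- simulation configuration -------------------------------------------

.default_groups <- c(
  "osteoglossiformes", "cypriniformes", "characiformes", "siluriformes",
  "salmoniformes", "esociformes", "perciformes", "cichliformes",
  "cyprinodontiformes", "tetraodontiformes"
)

.default_motif_anchors <- c(DRY = 148L, CWxP = 266L, NPxxY = 320L)

## reference positions of the eight sites planted as SREB3B-specific; the
## remainder of the pool is used when more sites are requested
.default_specific_positions <- c(132L, 165L, 184L, 217L, 292L, 293L, 296L, 372L)

.sreb_clusters <- c("SREB1", "SREB2", "SREB3A", "SREB3B")

species_names <- function(group_names, n_per_group) {
  unlist(lapply(group_names, function(g) sprintf("%s_%02d", g, seq_len(n_per_group))),
         use.names = FALSE)
}

default_loss_events <- function(group_names, n_per_group) {
  sp <- function(g, i) sprintf("%s_%02d", g, i)
  list(
    list(cluster = "SREB1",  clade = sp("characiformes", 1:4),      mode = "gene_loss"),
    list(cluster = "SREB3A", clade = sp("cyprinodontiformes", 1:8), mode = "gene_loss"),
    list(cluster = "SREB3B", clade = sp("osteoglossiformes", 1:8),  mode = "gene_loss"),
    list(cluster = "SREB3B", clade = sp("cypriniformes", 1:8),      mode = "gene_loss"),
    list(cluster = "SREB3B", clade = sp("characiformes", 1:8),      mode = "gene_loss"),
    list(cluster = "SREB3B", clade = sp("cyprinodontiformes", 5),   mode = "assembly_gap")
  )
}

default_qc_failures <- function() {
  list(
    list(cluster = "SREB1",  species = "siluriformes_01",      failure = "tm_count", k = 6L),
    list(cluster = "SREB2",  species = "osteoglossiformes_01", failure = "tm_count", k = 5L),
    list(cluster = "SREB2",  species = "cypriniformes_01",     failure = "tm_count", k = 6L),
    list(cluster = "SREB3A", species = "salmoniformes_01",     failure = "tm_count", k = 8L),
    list(cluster = "SREB3A", species = "salmoniformes_02",     failure = "tm_count", k = 8L),
    list(cluster = "SREB3A", species = "salmoniformes_03",     failure = "tm_count", k = 8L),
    list(cluster = "SREB3B", species = "perciformes_01",       failure = "tm_count", k = 5L)
  )
}

default_qpcr_config <- function() {
  genes <- c("sreb1", "sreb2", "sreb3a", "smim20", "r18s", "gapdh")
  list(
    genes = genes,
    reference_genes = c("r18s", "gapdh"),
    groups = c("TS", "OVV"),
    calibrator = "TS",
    n_per_group = c(TS = 8L, OVV = 8L),
    planted_fold_changes = list(
      sreb1 = c(TS = 1, OVV = 0.5), sreb2 = c(TS = 1, OVV = 2),
      sreb3a = c(TS = 1, OVV = 4), smim20 = c(TS = 1, OVV = 8),
      r18s = c(TS = 1, OVV = 1), gapdh = c(TS = 1, OVV = 5)
    ),
    ct_sd = 0.15,
    efficiency = c(sreb1 = 0.95, sreb2 = 0.97, sreb3a = 0.93,
                   smim20 = 1.0, r18s = 0.99, gapdh = 0.96),
    intercept = c(sreb1 = 24, sreb2 = 23, sreb3a = 25, smim20 = 24,
                  r18s = 10, gapdh = 21),
    base_quantity = c(sreb1 = 0.05, sreb2 = 0.05, sreb3a = 0.05,
                      smim20 = 0.05, r18s = 5, gapdh = 0.5),
    dilution_points = 5L,
    dilution_factor = 10,
    n_curve_replicates = 3L,
    n_well_replicates = 2L,
    input_rna_ug = 2.5
  )
}

#' Protein architecture used by the sequence simulator
#'
#' Describes a canonical 7TM receptor body: an N-terminal extracellular
#' region, `n_tm` transmembrane runs of `tm_len` hydrophobic residues
#' separated by hydrophilic loops, and a C-terminal tail. Positions are
#' 1-based on the ungapped protein.
#'
#' @param n_term length of the N-terminal region before TM1
#' @param tm_len length of each transmembrane run
#' @param loop_len length of the loops between consecutive runs
#' @param n_tm number of transmembrane runs
#' @param c_term length of the C-terminal tail after the last run
#' @return list with `length`, `tm_segments` (two-column matrix of
#'   start/end residue positions) and `region` (per-position `"tm"`/`"loop"`)
#' @export
protein_architecture <- function(n_term = 40L, tm_len = 21L, loop_len = 22L,
                                 n_tm = 7L, c_term = 56L) {
  starts <- n_term + 1L + (seq_len(n_tm) - 1L) * (tm_len + loop_len)
  segs <- cbind(start = starts, end = starts + tm_len - 1L)
  len <- n_term + n_tm * tm_len + (n_tm - 1L) * loop_len + c_term
  region <- rep("loop", len)
  for (i in seq_len(n_tm)) region[segs[i, 1]:segs[i, 2]] <- "tm"
  list(length = len, tm_segments = segs, region = region,
       n_term = n_term, tm_len = tm_len, loop_len = loop_len)
}

#' Build a simulation configuration
#'
#' The default configuration mirrors the comparative dataset the package's
#' analyses are designed for: 80 species in 10 order-like clades of 8, four
#' paralog clusters with differing per-site substitution probabilities,
#' planted gene losses (including loss of sreb3a across an entire
#' Cyprinodontiformes-like clade and one assembly-gap case), seven
#' quality-control failures with 5/6/8 transmembrane runs, eight planted
#' SREB3B-specific sites, canonical-motif deviations (DRY-D replaced by T
#' with a single exception, CWxP-C by L outside SREB1, NPxxY-Y by C, or S in
#' derived-clade SREB1), three divergent outgroup-like sequences, and a qPCR
#' experiment with planted fold changes. After quality filtering and
#' outgroup removal the default family contains 75/80/69/54 sequences in
#' SREB1/2/3A/3B.
#'
#' @param seed integer seed driving every random choice of the simulators
#' @param group_names clade ("order") names; each contributes
#'   `n_per_group` species named `<group>_<nn>`
#' @param n_per_group species per clade (power of two keeps all prefix
#'   blocks monophyletic)
#' @param tree `"balanced"` (deterministic ultrametric default), a Newick
#'   string over the species names, or `"random(<birth_rate>)"`
#' @param subst_prob named per-cluster per-site substitution probability per
#'   unit tree depth, each in `[0, 1]`
#' @param n_specific_sites named count of planted cluster-specific sites
#' @param loss_events list of `list(cluster, clade, mode)` with mode
#'   `"gene_loss"` or `"assembly_gap"`
#' @param duplication_events list of `list(cluster, clade, new_cluster_name)`
#' @param qc_failures list of `list(cluster, species, failure, k)` where
#'   failure is `"tm_count"` (with run count `k`) or `"truncated_orf"`
#' @param n_outgroups number of divergent outgroup-like sequences
#' @param divergence_pool number of sites carrying cluster-diagnostic
#'   divergence (each site separates exactly one pair of clusters)
#' @param derived_groups clades treated as "derived" for the SREB1
#'   NPxxY-position C-to-S replacement
#' @param dry_exception species whose SREB1 keeps the canonical D at the
#'   DRY anchor (everything else carries T)
#' @param architecture see [protein_architecture()]
#' @param qpcr qPCR experiment description; see `default_qpcr_config()`
#' @return object of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       group_names = .default_groups,
                       n_per_group = 8L,
                       tree = "balanced",
                       subst_prob = c(SREB1 = 0.030, SREB2 = 0.015,
                                      SREB3A = 0.040, SREB3B = 0.060),
                       n_specific_sites = c(SREB3B = 8L),
                       loss_events = NULL,
                       duplication_events = NULL,
                       qc_failures = NULL,
                       n_outgroups = 3L,
                       divergence_pool = 120L,
                       derived_groups = NULL,
                       dry_exception = "tetraodontiformes_08",
                       architecture = protein_architecture(),
                       qpcr = default_qpcr_config()) {
  default_world <- identical(group_names, .default_groups) && n_per_group == 8L
  if (is.null(loss_events))
    loss_events <- if (default_world) default_loss_events(group_names, n_per_group) else list()
  if (is.null(duplication_events))
    duplication_events <- if (default_world)
      list(list(cluster = "SREB2", clade = sprintf("osteoglossiformes_%02d", 1:2),
                new_cluster_name = "SREB2")) else list()
  if (is.null(qc_failures))
    qc_failures <- if (default_world) default_qc_failures() else list()
  if (is.null(derived_groups))
    derived_groups <- if (default_world) .default_groups[6:10] else character()

  stopifnot(all(subst_prob >= 0 & subst_prob <= 1),
            all(n_specific_sites >= 0),
            n_outgroups >= 0, n_per_group >= 1)
  clusters <- names(subst_prob)
  if (is.null(clusters) || anyDuplicated(clusters))
    stop("subst_prob must be uniquely named by cluster")
  bad <- setdiff(names(n_specific_sites), clusters)
  if (length(bad)) stop("n_specific_sites names unknown cluster: ", bad[1])

  species <- species_names(group_names, n_per_group)
  for (ev in c(loss_events, duplication_events)) {
    if (!all(ev$clade %in% species))
      stop("clade not found in tree: ", paste(setdiff(ev$clade, species), collapse = ", "))
    if (!ev$cluster %in% clusters) stop("unknown cluster in event: ", ev$cluster)
  }
  for (qc in qc_failures) {
    if (!qc$species %in% species) stop("qc_failure species not in tree: ", qc$species)
    if (!qc$failure %in% c("tm_count", "truncated_orf"))
      stop("unknown qc failure mode: ", qc$failure)
  }
  if (any(vapply(qpcr$planted_fold_changes, function(x) x[[qpcr$calibrator]], 1) != 1))
    stop("fold change of the calibrator group must be exactly 1.0")
  if (any(qpcr$efficiency < 0.8 | qpcr$efficiency > 1.1))
    stop("per-gene amplification efficiencies must lie in [0.8, 1.1]")

  structure(list(
    seed = as.integer(seed), group_names = group_names,
    n_per_group = as.integer(n_per_group), species = species, tree = tree,
    clusters = clusters, subst_prob = subst_prob,
    n_specific_sites = n_specific_sites, loss_events = loss_events,
    duplication_events = duplication_events, qc_failures = qc_failures,
    n_outgroups = as.integer(n_outgroups),
    divergence_pool = as.integer(divergence_pool),
    derived_groups = derived_groups, dry_exception = dry_exception,
    architecture = architecture,
    motif_anchors = .default_motif_anchors, qpcr = qpcr
  ), class = "sim_config")
}

## deterministic ultrametric Newick: recursive halving over units
.balanced_newick <- function(units, height, render) {
  if (length(units) == 1L) return(render(units[[1]], height))
  k <- ceiling(length(units) / 2)
  left <- .balanced_newick(units[seq_len(k)], height / 2, render)
  right <- .balanced_newick(units[-seq_len(k)], height / 2, render)
  sprintf("(%s,%s):%g", left, right, height / 2)
}

#' Resolve the species tree of a simulation configuration
#'
#' @param config a [sim_config()] object
#' @return an ultrametric `phylo` tree of depth 1 over `config$species`
#' @export
species_tree <- function(config) {
  spec <- config$tree
  if (identical(spec, "balanced")) {
    render_group <- function(g, h) {
      tips <- sprintf("%s_%02d", g, seq_len(config$n_per_group))
      if (length(tips) == 1L) return(sprintf("%s:%g", tips, h))
      .balanced_newick(as.list(tips), h, function(t, hh) sprintf("%s:%g", t, hh))
    }
    txt <- .balanced_newick(as.list(config$group_names), 1, render_group)
    txt <- sub(":[0-9.eE+-]+$", ";", txt)
    tr <- ape::read.tree(text = txt)
  } else if (grepl("^random\\(", spec)) {
    rate <- as.numeric(sub("^random\\(([0-9.]+)\\)$", "\\1", spec))
    tr <- ape::rphylo(length(config$species), birth = rate, death = 0)
    tr$tip.label <- config$species
  } else {
    tr <- ape::read.tree(text = spec)
    if (!setequal(tr$tip.label, config$species))
      stop("supplied Newick tree does not cover the configured species")
  }
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr
}
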