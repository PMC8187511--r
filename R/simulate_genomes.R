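## ---- synthetic genome (gene-order) generator ----------------------------

#' Default flanking-gene layout for each paralog locus
#'
#' The sreb3a locus is flanked upstream by foxp3b and downstream by suv39h1;
#' the sreb3b locus upstream by tspy and ppp1r3f and downstream by wdr13.
#' Loci for the other clusters use neutral symbols. Unknown clusters get a
#' generic locus so custom configurations remain usable.
#'
#' @param clusters cluster names
#' @return named list with `contig`, `upstream`, `downstream` per cluster
#' @export
default_loci <- function(clusters = .sreb_clusters) {
  known <- list(
    SREB1  = list(contig = "chr02", upstream = "eaf1",
                  downstream = "rab5a"),
    SREB2  = list(contig = "chr07", upstream = "sema5a",
                  downstream = "snx18"),
    SREB3A = list(contig = "chr11", upstream = "foxp3b",
                  downstream = "suv39h1"),
    SREB3B = list(contig = "chr14", upstream = c("tspy", "ppp1r3f"),
                  downstream = "wdr13")
  )
  out <- lapply(clusters, function(cl) {
    if (!is.null(known[[cl]])) known[[cl]]
    else list(contig = paste0("chr_", tolower(cl)),
              upstream = paste0(tolower(cl), "_up"),
              downstream = paste0(tolower(cl), "_dn"))
  })
  stats::setNames(out, clusters)
}

#' Simulate per-species gene-order annotations
#'
#' Places every family gene between its locus's conserved upstream and
#' downstream flanking genes. A `gene_loss` event removes only the family
#' gene (both flankers remain, the signature of a true loss); an
#' `assembly_gap` event removes the family gene and its downstream
#' flanker(s), mimicking a truncated contig. Coordinates are 1-based and
#' inclusive; flanking-gene losses never touch the outer anchor genes, so
#' every contig is still emitted.
#'
#' @param config a [sim_config()] object
#' @param family output of [simulate_family()] under the same config
#' @param loci locus layout, see [default_loci()]
#' @return named list of per-species data frames (species, symbol, contig,
#'   start, end, strand), class `sreb_genomes`
#' @export
simulate_genomes <- function(config, family, loci = default_loci(config$clusters)) {
  stopifnot(inherits(family, "sreb_family"))
  losses <- family$truth$losses
  genes <- family$genes
  out <- list()
  for (sp in config$species) {
    recs <- list()
    for (cl in config$clusters) {
      locus <- loci[[cl]]
      mode <- losses$mode[losses$species == sp & losses$cluster == cl]
      target_syms <- character()
      if (length(mode) == 0L) {
        ids <- genes$gene_id[genes$species == sp & genes$cluster_hint == cl]
        target_syms <- tolower(cl)
        if (length(ids) > 1L)          # duplicated copy sits beside the gene
          target_syms <- c(target_syms, paste0(tolower(cl), "b"))
      }
      downstream <- locus$downstream
      if (length(mode) && mode[1] == "assembly_gap") downstream <- character()
      syms <- c(paste0("edge_", tolower(cl), "_a"), locus$upstream,
                target_syms, downstream, paste0("edge_", tolower(cl), "_b"))
      n <- length(syms)
      start <- (seq_len(n) - 1L) * 1500L + 1L
      strand <- rep("+", n)
      strand[syms %in% locus$downstream] <- "-"
      recs[[cl]] <- data.frame(
        species = sp, symbol = syms, contig = locus$contig,
        start = start, end = start + 999L, strand = strand,
        stringsAsFactors = FALSE)
    }
    out[[sp]] <- do.call(rbind, recs)
    rownames(out[[sp]]) <- NULL
  }
  structure(out, class = "sreb_genomes")
}
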