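## ---- readers and writers -------------------------------------------------
## Writers emit fully deterministic bytes (fixed column order, no quoting,
## LF line endings) so identical configurations give identical files.

#' Write family genes as nucleotide FASTA
#'
#' Headers follow `species|gene_id|cluster_hint`.
#'
#' @param genes gene data frame from [simulate_family()] (or compatible)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_family_fasta <- function(genes, path) {
  if (inherits(genes, "sreb_family")) genes <- genes$genes
  hdr <- sprintf(">%s|%s|%s", genes$species, genes$gene_id, genes$cluster_hint)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(as.vector(rbind(hdr, genes$sequence)), con, sep = "\n")
  invisible(path)
}

#' Read a gene FASTA written by [write_family_fasta()]
#'
#' Headers without the `species|gene_id|cluster_hint` structure fall back to
#' using the whole header as both gene id and species.
#'
#' @param path FASTA file of nucleotide genes
#' @return data frame with gene_id, species, cluster_hint, sequence
#' @export
read_gene_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  get <- function(i, default) vapply(parts, function(p)
    if (length(p) >= i) p[i] else default(p), "")
  data.frame(
    gene_id = get(2L, function(p) p[1]),
    species = get(1L, function(p) p[1]),
    cluster_hint = get(3L, function(p) NA_character_),
    sequence = as.character(ss),
    stringsAsFactors = FALSE)
}

#' Write aligned or unaligned proteins as FASTA
#' @param seqs named character vector of (aligned) amino-acid sequences
#' @param path output file
#' @return `path`, invisibly
#' @export
write_protein_fasta <- function(seqs, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))),
             con, sep = "\n")
  invisible(path)
}

#' Write genome annotations as a BED-like TSV
#' @param genomes `sreb_genomes` list from [simulate_genomes()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_genomes_tsv <- function(genomes, path) {
  df <- do.call(rbind, unname(unclass(genomes)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Read genome annotations from a BED-like TSV
#' @param path TSV with columns species, symbol, contig, start, end, strand
#' @return `sreb_genomes` named list of per-species data frames
#' @export
read_genomes_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "symbol", "contig", "start", "end", "strand")
  if (!all(need %in% names(df)))
    stop("genome TSV must have columns: ", paste(need, collapse = ", "))
  out <- split(df, df$species)
  out <- lapply(out, function(x) { rownames(x) <- NULL; x })
  structure(out[unique(df$species)], class = "sreb_genomes")
}

#' Write genome annotations as GFF3
#' @param genomes `sreb_genomes` list from [simulate_genomes()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_genomes_gff3 <- function(genomes, path) {
  df <- do.call(rbind, unname(unclass(genomes)))
  lines <- c("##gff-version 3",
             sprintf("%s\tsrebscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_name=%s",
                     paste(df$species, df$contig, sep = ":"),
                     df$start, df$end, df$strand,
                     paste(df$species, df$symbol, sep = ":"), df$symbol))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read genome annotations from GFF3 written by [write_genomes_gff3()]
#' @param path GFF3 file
#' @return `sreb_genomes` named list of per-species data frames
#' @export
read_genomes_gff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  f <- strsplit(ln, "\t", fixed = TRUE)
  seqid <- vapply(f, `[`, "", 1L)
  sp_contig <- strsplit(seqid, ":", fixed = TRUE)
  attr9 <- vapply(f, `[`, "", 9L)
  sym <- sub(".*gene_name=([^;]+).*", "\\1", attr9)
  df <- data.frame(
    species = vapply(sp_contig, `[`, "", 1L),
    symbol = sym,
    contig = vapply(sp_contig, `[`, "", 2L),
    start = as.integer(vapply(f, `[`, "", 4L)),
    end = as.integer(vapply(f, `[`, "", 5L)),
    strand = vapply(f, `[`, "", 7L),
    stringsAsFactors = FALSE)
  out <- split(df, df$species)
  out <- lapply(out, function(x) { rownames(x) <- NULL; x })
  structure(out[unique(df$species)], class = "sreb_genomes")
}

#' Write a Ct table as CSV
#' @param ct_table data frame from [simulate_ct()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_ct_csv <- function(ct_table, path) {
  utils::write.csv(ct_table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Ct table CSV
#' @param path CSV with columns sample_id, group, gene, replicate, ct,
#'   input_rna_ug
#' @return data frame
#' @export
read_ct_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "gene", "replicate", "ct")
  if (!all(need %in% names(df)))
    stop("Ct CSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' Write the planted-truth manifest of a simulated family
#'
#' Emits a TSV of planted cluster-specific sites, a TSV of loss events and
#' a TSV of planted fold changes, so downstream checks need no R objects.
#'
#' @param family output of [simulate_family()]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_truth <- function(family, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- family$truth
  sites <- do.call(rbind, lapply(names(tr$specific_sites), function(cl)
    data.frame(cluster = cl, ref_position = tr$specific_sites[[cl]],
               target = vapply(as.character(tr$specific_sites[[cl]]),
                               function(p) tr$specific_residues[[p]][["target"]], ""),
               background = vapply(as.character(tr$specific_sites[[cl]]),
                                   function(p) tr$specific_residues[[p]][["background"]], ""))))
  if (is.null(sites))
    sites <- data.frame(cluster = character(), ref_position = integer(),
                        target = character(), background = character())
  utils::write.table(sites, file.path(dir, "truth_specific_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  utils::write.table(tr$losses, file.path(dir, "truth_losses.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  fc <- do.call(rbind, lapply(names(tr$fold_changes), function(g)
    data.frame(gene = g, group = names(tr$fold_changes[[g]]),
               fold_change = unname(tr$fold_changes[[g]]))))
  utils::write.table(fc, file.path(dir, "truth_fold_changes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(dir)
}
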