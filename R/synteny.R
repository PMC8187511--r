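## ---- microsynteny presence/absence calling ------------------------------

## case-fold and strip a "-like"/"_like" suffix
.canon <- function(x) sub("[-_]like$", "", tolower(x))

## drop a single trailing paralog letter after a digit (suv39h1a -> suv39h1)
.strip_paralog <- function(x) sub("(?<=[0-9])[a-z]$", "", x, perl = TRUE)

#' Do two gene symbols refer to the same (homologous) gene?
#'
#' Matching is exact after case-folding and removal of a "-like" suffix;
#' in addition a single trailing paralog letter may be stripped from either
#' side (suv39h1a matches suv39h1), but stripping both sides is never
#' allowed, so sreb3a and sreb3b stay distinct. A synonym table extends the
#' equivalence.
#'
#' @param a,b gene symbols
#' @param synonyms optional two-column data frame (symbol, synonym)
#' @return logical
#' @export
symbols_match <- function(a, b, synonyms = NULL) {
  ca <- .canon(a); cb <- .canon(b)
  hit <- ca == cb | .strip_paralog(ca) == cb | ca == .strip_paralog(cb)
  if (!is.null(synonyms)) {
    syn <- apply(synonyms, 1L, function(r) {
      (.canon(r[1]) == ca & .canon(r[2]) == cb) |
        (.canon(r[1]) == cb & .canon(r[2]) == ca)
    })
    hit <- hit | any(syn)
  }
  hit
}

.match_rows <- function(symbols, query, synonyms = NULL)
  which(vapply(symbols, symbols_match, NA, b = query, synonyms = synonyms))

#' Species-by-gene presence matrix from screening results
#'
#' present: at least one Dataset-1-passing hit; incomplete: only hits that
#' fail the screen (used solely as presence/absence evidence); absent: no
#' hit at all.
#'
#' @param screens data frame from [screen_genes()] (needs species,
#'   cluster_hint, dataset1_pass)
#' @param species optional full species list (rows); defaults to those seen
#' @param genes optional full gene list (columns); defaults to those seen
#' @return data frame: species, gene, status in present/incomplete/absent
#' @export
presence_matrix <- function(screens, species = NULL, genes = NULL) {
  if (is.null(species)) species <- unique(screens$species)
  if (is.null(genes)) genes <- unique(screens$cluster_hint)
  out <- expand.grid(species = species, gene = genes,
                     stringsAsFactors = FALSE)
  out$status <- vapply(seq_len(nrow(out)), function(i) {
    hit <- screens$species == out$species[i] &
      screens$cluster_hint == out$gene[i]
    if (!any(hit)) return("absent")
    if (any(screens$dataset1_pass[hit])) "present" else "incomplete"
  }, "")
  out
}

#' Classify one gene's locus from flanking genes
#'
#' Locates the configured upstream and downstream flanking genes, and calls
#' the target: `present` when the target lies between them (or anywhere in
#' the genome when flankers are missing), `lost` when both flankers sit
#' intact on one contig with no target between them and no target anywhere
#' else, `assembly_gap` when at least one flanker is missing from the
#' flanked contig (including flankers split across contigs), and
#' `inconclusive` when the flankers overlap, are unordered, or exceed the
#' span limits. A target found anywhere in the genome is never called lost.
#'
#' @param genome one species' annotation (data frame: symbol, contig,
#'   start, end, strand)
#' @param target target gene symbol
#' @param upstream,downstream flanking gene symbols (vectors allowed; the
#'   innermost is used for the interval)
#' @param max_span_genes,max_span_bp span limits between the flankers
#' @param synonyms optional synonym table for [symbols_match()]
#' @return list of class `synteny_call`: `species`, `target`,
#'   `upstream_flank_status`, `downstream_flank_status`, `interval_genes`,
#'   `call`
#' @export
call_synteny <- function(genome, target, upstream, downstream,
                         max_span_genes = 50L, max_span_bp = 2e6,
                         synonyms = NULL) {
  for (fl in c(upstream, downstream))
    if (symbols_match(target, fl, synonyms))
      stop("target symbol equal to a flanker symbol: ", fl)
  species <- if ("species" %in% names(genome)) genome$species[1] else NA_character_

  target_rows <- .match_rows(genome$symbol, target, synonyms)
  target_anywhere <- length(target_rows) > 0L

  ## innermost flankers define the interval
  up_sym <- upstream[length(upstream)]
  dn_sym <- downstream[1L]
  up_rows <- .match_rows(genome$symbol, up_sym, synonyms)
  dn_rows <- .match_rows(genome$symbol, dn_sym, synonyms)

  ## choose a shared contig if one exists
  shared <- intersect(genome$contig[up_rows], genome$contig[dn_rows])
  mk <- function(up_st, dn_st, interval, call)
    structure(list(species = species, target = target,
                   upstream_flank_status = up_st,
                   downstream_flank_status = dn_st,
                   interval_genes = interval, call = call),
              class = "synteny_call")

  if (!length(shared)) {
    ## no contig carries both flankers
    up_st <- if (length(up_rows)) "found" else "missing"
    dn_st <- if (length(dn_rows)) "missing" else "missing"
    if (length(up_rows) && length(dn_rows)) {
      ## flankers split across contigs: treat the locus as broken
      up_st <- "found"; dn_st <- "missing"
    } else if (length(dn_rows) && !length(up_rows)) {
      up_st <- "missing"; dn_st <- "found"
    }
    call <- if (target_anywhere) "present" else "assembly_gap"
    return(mk(up_st, dn_st, character(), call))
  }

  contig <- shared[1L]
  on_contig <- genome[genome$contig == contig, , drop = FALSE]
  on_contig <- on_contig[order(on_contig$start), , drop = FALSE]
  ui <- .match_rows(on_contig$symbol, up_sym, synonyms)[1L]
  di <- .match_rows(on_contig$symbol, dn_sym, synonyms)[1L]
  lo <- min(ui, di); hi <- max(ui, di)
  if (ui == di || on_contig$end[lo] >= on_contig$start[hi])
    return(mk("found", "found", character(), "inconclusive"))
  n_between <- hi - lo - 1L
  span_bp <- on_contig$start[hi] - on_contig$end[lo]
  if (n_between > max_span_genes || span_bp > max_span_bp)
    return(mk("found", "found", character(), "inconclusive"))
  interval <- on_contig$symbol[seq(lo + 1L, length.out = n_between)]
  in_interval <- any(vapply(interval, symbols_match, NA, b = target,
                            synonyms = synonyms))
  call <- if (in_interval) "present"
  else if (target_anywhere) "present"   # genome-wide rescue
  else "lost"
  mk("found", "found", interval, call)
}

#' Synteny calls for one locus across a genome collection
#'
#' @param genomes `sreb_genomes` list (see [simulate_genomes()] /
#'   [read_genomes_tsv()])
#' @param target,upstream,downstream,... passed to [call_synteny()]
#' @return data frame with one row per species
#' @export
call_synteny_all <- function(genomes, target, upstream, downstream, ...) {
  rows <- lapply(names(genomes), function(sp) {
    sc <- call_synteny(genomes[[sp]], target, upstream, downstream, ...)
    data.frame(species = sp, target = target,
               upstream_flank_status = sc$upstream_flank_status,
               downstream_flank_status = sc$downstream_flank_status,
               n_interval_genes = length(sc$interval_genes),
               call = sc$call, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plain-text gene-order diagram of one locus
#'
#' @param genome one species' annotation data frame
#' @param contig contig to draw
#' @return character string, one gene per arrow
#' @export
locus_diagram <- function(genome, contig) {
  g <- genome[genome$contig == contig, , drop = FALSE]
  g <- g[order(g$start), , drop = FALSE]
  paste(sprintf("%s(%s)", g$symbol, g$strand), collapse = " -> ")
}
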