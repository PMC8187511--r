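## ---- candidate-gene verification ----------------------------------------

#' Find the longest ATG-initiated open reading frame
#'
#' Scans all six frames of a nucleotide sequence for ATG-initiated,
#' stop-terminated reading frames and returns the translation of the
#' longest. Ties are broken in favour of the earlier start on the input
#' coordinates, then the plus strand. Ambiguous codons (containing N)
#' translate to X and never terminate a frame.
#'
#' @param sequence IUPAC DNA string (A/C/G/T/N)
#' @param gene_id optional identifier carried through to the result
#' @param min_codons minimum ORF length, in codons, below which the gene is
#'   flagged rather than translated
#' @return list of class `protein_record`: `gene_id`, `aa_sequence` (no
#'   stop), `strand`, `frame` (0..2), `orf_span` (1-based inclusive on the
#'   input, including the stop codon), `ok`, `reason`
#' @export
find_longest_orf <- function(sequence, gene_id = NULL, min_codons = 50L) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence) || grepl("[^ACGTN]", sequence))
    stop("sequence must be a non-empty string over A/C/G/T/N")
  L <- nchar(sequence)
  candidates <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
    for (frame in 0:2) {
      n_codon <- (L - frame) %/% 3L
      if (n_codon < 2L) next
      sub <- substr(s, frame + 1L, frame + 3L * n_codon)
      aa <- as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                               if.fuzzy.codon = "X"))
      codons <- strsplit(aa, "")[[1]]
      stops <- which(codons == "*")
      if (!length(stops)) next
      seg_start <- 1L
      for (st in stops) {
        if (st > seg_start) {
          ms <- which(codons[seg_start:(st - 1L)] == "M")
          if (length(ms)) {
            m <- seg_start + ms[1] - 1L
            aa_seq <- paste(codons[m:(st - 1L)], collapse = "")
            ## map codon indices back to input coordinates
            nt_start <- frame + 3L * (m - 1L) + 1L
            nt_end <- frame + 3L * st
            span <- if (strand == "+") c(nt_start, nt_end) else
              c(L - nt_end + 1L, L - nt_start + 1L)
            candidates[[length(candidates) + 1L]] <- list(
              aa = aa_seq, strand = strand, frame = frame, span = span)
          }
        }
        seg_start <- st + 1L
      }
    }
  }
  if (length(candidates)) {
    len <- vapply(candidates, function(x) nchar(x$aa), 0L)
    keep <- len >= min_codons
    candidates <- candidates[keep]; len <- len[keep]
  }
  if (!length(candidates)) {
    return(structure(list(gene_id = gene_id, aa_sequence = NA_character_,
                          strand = NA_character_, frame = NA_integer_,
                          orf_span = c(NA_integer_, NA_integer_),
                          ok = FALSE, reason = "no_orf"),
                     class = "protein_record"))
  }
  ord <- order(-vapply(candidates, function(x) nchar(x$aa), 0L),
               vapply(candidates, function(x) x$span[1], 0L),
               vapply(candidates, function(x) x$strand != "+", NA))
  best <- candidates[[ord[1]]]
  structure(list(gene_id = gene_id, aa_sequence = best$aa,
                 strand = best$strand, frame = best$frame,
                 orf_span = as.integer(best$span), ok = TRUE, reason = NA_character_),
            class = "protein_record")
}

#' Predict transmembrane segments by Kyte-Doolittle hydropathy
#'
#' Computes the mean Kyte-Doolittle hydropathy over a sliding window;
#' maximal runs of window centres above the threshold, expanded to the full
#' residue extent covered by their windows, become candidate segments.
#' Segments shorter than `min_segment` residues are discarded, then
#' segments separated by at most `merge_gap` residues are merged.
#'
#' @param protein a `protein_record` or an amino-acid string
#' @param window sliding-window width (odd)
#' @param threshold mean-hydropathy cutoff for a window centre
#' @param min_segment minimum retained segment length, residues
#' @param merge_gap maximum gap between merged segments, residues
#' @return list of class `tm_annotation`: `segments` (two-column matrix of
#'   1-based start/end residue coordinates), `count`, `reason`
#' @export
predict_tm <- function(protein, window = 19L, threshold = 1.6,
                       min_segment = 15L, merge_gap = 3L) {
  aa <- if (inherits(protein, "protein_record")) protein$aa_sequence else protein
  empty <- function(reason) structure(
    list(segments = matrix(integer(), 0, 2,
                           dimnames = list(NULL, c("start", "end"))),
         count = 0L, reason = reason), class = "tm_annotation")
  if (is.na(aa)) return(empty("no_orf"))
  L <- nchar(aa)
  if (L < window) return(empty("too_short"))
  kd <- .kd_scale[strsplit(aa, "")[[1]]]
  kd[is.na(kd)] <- 0
  h <- (window - 1L) %/% 2L
  means <- as.numeric(stats::filter(kd, rep(1 / window, window), sides = 2))
  centers <- which(!is.na(means) & means > threshold)
  if (!length(centers)) return(empty(NA_character_))
  runs <- split(centers, cumsum(c(1L, diff(centers) != 1L)))
  segs <- do.call(rbind, lapply(runs, function(r)
    c(max(1L, min(r) - h), min(L, max(r) + h))))
  segs <- segs[segs[, 2] - segs[, 1] + 1L >= min_segment, , drop = FALSE]
  if (nrow(segs) > 1L) {
    merged <- list(segs[1, ])
    for (i in 2:nrow(segs)) {
      last <- merged[[length(merged)]]
      if (segs[i, 1] - last[2] - 1L <= merge_gap)
        merged[[length(merged)]] <- c(last[1], segs[i, 2])
      else merged[[length(merged) + 1L]] <- segs[i, ]
    }
    segs <- do.call(rbind, merged)
  }
  dimnames(segs) <- list(NULL, c("start", "end"))
  structure(list(segments = segs, count = nrow(segs), reason = NA_character_),
            class = "tm_annotation")
}

#' Apply the family inclusion filters
#'
#' A candidate is analysis-grade (Dataset 2) when its translation is close
#' to the expected receptor length (370 aa within `len_tol`) and shows all
#' seven transmembrane runs; it still counts as presence/absence evidence
#' (Dataset 1) with at least five runs.
#'
#' @param protein a `protein_record` from [find_longest_orf()]
#' @param tm a `tm_annotation` from [predict_tm()]
#' @param len_target expected protein length, residues
#' @param len_tol tolerated relative deviation from `len_target`
#' @param tm_min minimum run count for Dataset 1
#' @param tm_exact run count required for Dataset 2
#' @return list of class `screen_result`: `gene_id`, `aa_length`,
#'   `length_ok`, `tm_count`, `dataset1_pass`, `dataset2_pass`, `reason`
#' @export
apply_filters <- function(protein, tm, len_target = 370L, len_tol = 0.15,
                          tm_min = 5L, tm_exact = 7L) {
  if (!protein$ok) {
    return(structure(list(gene_id = protein$gene_id, aa_length = NA_integer_,
                          length_ok = FALSE, tm_count = 0L,
                          dataset1_pass = FALSE, dataset2_pass = FALSE,
                          reason = "no_orf"), class = "screen_result"))
  }
  len <- nchar(protein$aa_sequence)
  ## +/- 15% of 370 gives the inclusive window 314..426
  length_ok <- len >= floor(len_target * (1 - len_tol)) &&
    len <= ceiling(len_target * (1 + len_tol))
  d1 <- length_ok && tm$count >= tm_min
  d2 <- length_ok && tm$count == tm_exact
  reason <- if (d2) "pass" else paste(
    c(if (!length_ok) sprintf("length_%d_outside_target", len),
      if (tm$count != tm_exact) sprintf("tm_count_%d", tm$count)),
    collapse = ";")
  structure(list(gene_id = protein$gene_id, aa_length = len,
                 length_ok = length_ok, tm_count = tm$count,
                 dataset1_pass = d1, dataset2_pass = d2, reason = reason),
            class = "screen_result")
}

#' Screen a table of candidate genes
#'
#' Runs [find_longest_orf()], [predict_tm()] and [apply_filters()] over a
#' gene table and returns one row per gene.
#'
#' @param genes data frame with gene_id, species, cluster_hint, sequence
#'   (e.g. from [simulate_family()] or [read_gene_fasta()])
#' @param ... passed on to the three stage functions
#' @return data frame with screening flags and the translated protein
#' @export
screen_genes <- function(genes, ...) {
  dots <- list(...)
  take <- function(f) dots[intersect(names(dots), names(formals(f)))]
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    pr <- do.call(find_longest_orf,
                  c(list(genes$sequence[i], gene_id = genes$gene_id[i]),
                    take(find_longest_orf)))
    tm <- do.call(predict_tm, c(list(pr), take(predict_tm)))
    sr <- do.call(apply_filters, c(list(pr, tm), take(apply_filters)))
    data.frame(gene_id = genes$gene_id[i], species = genes$species[i],
               cluster_hint = genes$cluster_hint[i],
               aa_length = if (is.na(sr$aa_length)) NA_integer_ else sr$aa_length,
               tm_count = sr$tm_count, tm1_start = if (tm$count > 0)
                 tm$segments[1, "start"] else NA_integer_,
               length_ok = sr$length_ok, dataset1_pass = sr$dataset1_pass,
               dataset2_pass = sr$dataset2_pass, reason = sr$reason,
               protein = if (pr$ok) pr$aa_sequence else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
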