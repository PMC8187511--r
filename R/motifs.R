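## ---- canonical GPCR motif scanning --------------------------------------

.canonical_motifs <- c(DRY = "DRY", CWxP = "CWxP", NPxxY = "NPxxY")

#' Scan canonical class-A GPCR motifs for deviations
#'
#' Class-A GPCRs carry DRY at the cytoplasmic end of TM3, CWxP in TM6 and
#' NPxxY in TM7. Given the reference position of each motif start, reports
#' the modal residue and conservation fraction at every motif position, per
#' cluster and pooled across all labelled rows, and flags deviations from
#' the canonical letter ('x' wildcard positions are never flagged).
#' Deviations restricted to a subclade can be examined by passing the
#' subclade's sequence ids as `ids`.
#'
#' @param msa a `sreb_msa` with cluster labels
#' @param motif_anchors named integer vector: reference position of the
#'   first residue of each motif (names among DRY, CWxP, NPxxY)
#' @param ids optional subset of sequence ids (a clade filter); statistics
#'   are then computed on that subset only
#' @param gap_policy passed to [profile_columns()]
#' @return data frame: `motif`, `offset` (0-based within the motif),
#'   `ref_position`, `canonical`, `cluster` (including `"(pooled)"`),
#'   `modal`, `conservation`, `conservation_pct` (half-up, 1 decimal),
#'   `deviation` (logical)
#' @export
scan_motifs <- function(msa, motif_anchors, ids = NULL,
                        gap_policy = c("divergent", "ignore")) {
  gap_policy <- match.arg(gap_policy)
  if (is.null(names(motif_anchors)) ||
      !all(names(motif_anchors) %in% names(.canonical_motifs)))
    stop("motif_anchors must be named among: ",
         paste(names(.canonical_motifs), collapse = ", "))
  if (!is.null(ids)) msa <- subset_msa(msa, union(ids, msa$reference_id))
  profiles <- profile_columns(msa, gap_policy = gap_policy)
  rp <- ref_positions(msa)
  out <- list()
  for (motif in names(motif_anchors)) {
    canon <- strsplit(.canonical_motifs[[motif]], "")[[1]]
    pos <- motif_anchors[[motif]] + seq_along(canon) - 1L
    if (any(!pos %in% rp))
      stop("motif anchor outside the alignment: ", motif)
    cols <- ref_to_column(msa, pos)
    for (k in seq_along(canon)) {
      pc <- profiles[profiles$column == cols[k], , drop = FALSE]
      wildcard <- canon[k] == "x"
      out[[length(out) + 1L]] <- data.frame(
        motif = motif, offset = k - 1L, ref_position = pos[k],
        canonical = canon[k], cluster = pc$cluster, modal = pc$modal,
        conservation = pc$conservation,
        conservation_pct = round_half_up(100 * pc$conservation, 1),
        deviation = if (wildcard) FALSE else
          !is.na(pc$modal) & pc$modal != canon[k],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
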