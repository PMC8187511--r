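## ---- per-cluster conservation profiling ---------------------------------

.pooled_label <- "(pooled)"

#' Per-column, per-cluster conservation profiles
#'
#' For every alignment column and every cluster (plus a pooled all-cluster
#' profile) computes the modal residue (ties broken alphabetically, gaps
#' never modal), the number of divergent rows and a conserved flag. Under
#' the default gap policy a gap counts as a divergent residue: a deletion is
#' not conservation of the modal residue. A column is conserved within a
#' cluster when it shows at most `max_divergent` divergent rows.
#'
#' @param msa a `sreb_msa` with cluster labels
#' @param max_divergent divergence tolerance defining the conserved flag
#' @param gap_policy `"divergent"` (gaps count against conservation) or
#'   `"ignore"` (gapped rows are dropped from the column's denominator)
#' @return data frame with one row per column x cluster: `column`,
#'   `ref_position`, `masked`, `cluster`, `n`, `n_gap`, `modal`,
#'   `modal_count`, `divergent_count`, `conserved`, `conservation`
#' @export
profile_columns <- function(msa, max_divergent = 3L,
                            gap_policy = c("divergent", "ignore")) {
  gap_policy <- match.arg(gap_policy)
  labels <- msa$clusters
  if (all(is.na(labels))) stop("cluster labels are required")
  m <- seq_matrix(msa$seqs, msa$ids)
  lv <- c(.amino_acids[order(.amino_acids)], "-")
  gap_i <- length(lv)
  codes <- matrix(match(m, lv), nrow(m), ncol(m))
  if (anyNA(codes)) codes[is.na(codes)] <- gap_i  # unknowns behave as gaps
  rp <- ref_positions(msa)

  groups <- sort(unique(stats::na.omit(labels)))
  member <- lapply(groups, function(g) which(!is.na(labels) & labels == g))
  names(member) <- groups
  sizes <- lengths(member)
  if (any(sizes == 0L)) {
    warning("omitting empty cluster(s): ",
            paste(groups[sizes == 0L], collapse = ", "))
    member <- member[sizes > 0L]
  }
  member[[.pooled_label]] <- which(!is.na(labels))

  out <- vector("list", length(member))
  for (g in seq_along(member)) {
    rows <- member[[g]]
    n <- length(rows)
    modal <- character(msa$n_cols); modal_count <- integer(msa$n_cols)
    n_gap <- integer(msa$n_cols)
    for (j in seq_len(msa$n_cols)) {
      tb <- tabulate(codes[rows, j], nbins = gap_i)
      n_gap[j] <- tb[gap_i]
      tb[gap_i] <- 0L
      w <- which.max(tb)               # first max = alphabetical tie-break
      if (tb[w] == 0L) { modal[j] <- NA_character_; modal_count[j] <- 0L }
      else { modal[j] <- lv[w]; modal_count[j] <- tb[w] }
    }
    denom <- if (gap_policy == "divergent") rep(n, msa$n_cols) else n - n_gap
    divergent <- denom - modal_count
    out[[g]] <- data.frame(
      column = seq_len(msa$n_cols), ref_position = rp, masked = msa$masked,
      cluster = names(member)[g], n = n, n_gap = n_gap, modal = modal,
      modal_count = modal_count, divergent_count = divergent,
      conserved = divergent <= max_divergent,
      conservation = ifelse(denom > 0, modal_count / denom, NA_real_),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "max_divergent") <- max_divergent
  attr(res, "gap_policy") <- gap_policy
  res
}

#' Minimum conservation percentage implied by a divergence tolerance
#'
#' With at most `max_divergent` divergent residues tolerated in a cluster
#' of n sequences, a conserved column has at least
#' `100 * (n - max_divergent) / n` percent of rows agreeing; the value is
#' reported rounded half-up to one decimal, the convention used for printed
#' thresholds (e.g. 96.3 for n = 80).
#'
#' @param n cluster size (must exceed `max_divergent`)
#' @param max_divergent divergence tolerance
#' @return percentage, one decimal
#' @export
min_conservation_pct <- function(n, max_divergent = 3L) {
  if (any(n <= max_divergent)) stop("cluster size must exceed max_divergent")
  round_half_up(100 * (n - max_divergent) / n, 1)
}

#' Sites conserved everywhere but divergent in one target cluster
#'
#' Reports reference positions where (a) each background cluster is
#' conserved and all background clusters share the same modal residue,
#' (b) the target cluster is conserved, and (c) the target's modal residue
#' differs from the shared background residue. With
#' `require_shared_background = FALSE` condition (a) relaxes to each
#' background being conserved with any residues, all different from the
#' target's.
#'
#' @param profiles output of [profile_columns()]
#' @param target_cluster cluster whose diagnostic sites are sought
#' @param background_clusters the clusters required to agree
#' @param require_shared_background strict (default) or relaxed background
#'   consensus, see above
#' @return data frame sorted by `ref_position`: `ref_position`, `column`,
#'   `consensus_other`, `consensus_target`, and one
#'   `conservation_<cluster>` column per cluster plus the pooled profile
#' @export
find_cluster_specific_sites <- function(profiles, target_cluster,
                                        background_clusters,
                                        require_shared_background = TRUE) {
  if (target_cluster %in% background_clusters)
    stop("target cluster cannot be among the background clusters")
  ok_cols <- !profiles$masked & !is.na(profiles$ref_position)
  p <- profiles[ok_cols, , drop = FALSE]
  cols <- sort(unique(p$column))
  keep <- list()
  for (cc in cols) {
    pc <- p[p$column == cc, , drop = FALSE]
    tg <- pc[pc$cluster == target_cluster, , drop = FALSE]
    bg <- pc[pc$cluster %in% background_clusters, , drop = FALSE]
    if (nrow(tg) != 1L || nrow(bg) != length(background_clusters)) next
    if (!all(bg$conserved) || !tg$conserved) next
    if (is.na(tg$modal) || anyNA(bg$modal)) next
    if (require_shared_background) {
      if (length(unique(bg$modal)) != 1L) next
      if (tg$modal == bg$modal[1]) next
      consensus_other <- bg$modal[1]
    } else {
      if (any(bg$modal == tg$modal)) next
      consensus_other <- if (length(unique(bg$modal)) == 1L)
        bg$modal[1] else NA_character_
    }
    row <- data.frame(ref_position = tg$ref_position, column = cc,
                      consensus_other = consensus_other,
                      consensus_target = tg$modal, stringsAsFactors = FALSE)
    for (cl in c(background_clusters, target_cluster, .pooled_label)) {
      v <- pc$conservation[pc$cluster == cl]
      row[[paste0("conservation_", cl)]] <- if (length(v)) v else NA_real_
    }
    keep[[length(keep) + 1L]] <- row
  }
  if (!length(keep)) {
    out <- data.frame(ref_position = integer(), column = integer(),
                      consensus_other = character(),
                      consensus_target = character(), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, keep)
  out <- out[order(out$ref_position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
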