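## ---- paralog-cluster assignment -----------------------------------------

## integer-code an MSA for the compiled p-distance kernel
.msa_codes <- function(msa) {
  m <- seq_matrix(msa$seqs, msa$ids)
  lv <- c(.amino_acids, "X")
  codes <- matrix(match(m, lv), nrow(m), ncol(m))
  codes[is.na(codes)] <- 0L            # gaps / unknowns
  storage.mode(codes) <- "integer"
  codes
}

#' Pairwise p-distances from a protein alignment
#'
#' p-distance = mismatches / comparable (both-ungapped) aligned positions.
#' Pairs with no comparable columns get distance 1 with a warning.
#'
#' @param msa a `sreb_msa`
#' @return object of class `dist_matrix`: list with `labels` and symmetric
#'   matrix `d`
#' @export
pairwise_distances <- function(msa) {
  codes <- .msa_codes(msa)
  res <- pdist_cpp(codes, 0L)
  if (any(res$empty))
    warning("sequence pair(s) share no comparable columns; distance set to 1")
  d <- res$d
  dimnames(d) <- list(msa$ids, msa$ids)
  structure(list(labels = msa$ids, d = d), class = "dist_matrix")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining with negative branch lengths clamped to zero.
#'
#' @param d a `dist_matrix` from [pairwise_distances()] (or a plain
#'   symmetric matrix with dimnames)
#' @return a `phylo` tree
#' @export
nj_tree <- function(d) {
  m <- if (inherits(d, "dist_matrix")) d$d else d
  if (nrow(m) < 3L) stop("neighbor-joining needs at least 3 sequences")
  tr <- ape::nj(m)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap cluster assignment from an alignment
#'
#' Resamples alignment columns with replacement, rebuilds a neighbor-joining
#' tree per replicate, roots it (on the designated outgroup, else at the
#' midpoint), and records for each candidate cluster the fraction of
#' replicates in which its hinted members are monophyletic. A sequence is
#' assigned its hinted cluster when that cluster's support reaches
#' `support_threshold`; sequences with no hint, with a hint outside
#' `candidate_clusters`, or in a poorly supported cluster are UNASSIGNED.
#'
#' @param msa a `sreb_msa`
#' @param hints named cluster hints (names = sequence ids); NA allowed
#' @param n_boot bootstrap replicates
#' @param seed integer seed for the resampling
#' @param support_threshold minimum support for an assignment
#' @param outgroup optional sequence id(s) used to root every replicate
#' @param candidate_clusters clusters eligible for assignment (default: all
#'   hinted clusters not in the outgroup)
#' @return list of class `cluster_assignment`: `assignments` (data frame
#'   gene_id, cluster_hint, assigned, support), `support` (named vector),
#'   `n_boot`, `tree` (NJ tree on the full alignment)
#' @export
bootstrap_clusters <- function(msa, hints, n_boot = 100L, seed = 1L,
                               support_threshold = 0.7, outgroup = NULL,
                               candidate_clusters = NULL) {
  if (msa$n_cols < 10L) stop("alignment too short to resample")
  ids <- msa$ids
  hint <- stats::setNames(rep(NA_character_, length(ids)), ids)
  common <- intersect(names(hints), ids)
  hint[common] <- unname(hints[common])
  if (!is.null(outgroup)) {
    if (!all(outgroup %in% ids)) stop("outgroup id(s) not in the alignment")
    hint[outgroup] <- NA_character_
  }
  if (is.null(candidate_clusters))
    candidate_clusters <- sort(unique(stats::na.omit(hint)))
  members <- lapply(candidate_clusters, function(cl) ids[!is.na(hint) & hint == cl])
  names(members) <- candidate_clusters
  members <- members[lengths(members) > 0L]

  codes <- .msa_codes(msa)
  root_tree <- function(tr) {
    if (!is.null(outgroup)) ape::root(tr, outgroup = outgroup,
                                      resolve.root = TRUE)
    else phangorn::midpoint(tr)
  }
  hits <- stats::setNames(numeric(length(members)), names(members))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      cols <- sample.int(ncol(codes), ncol(codes), replace = TRUE)
      res <- pdist_cpp(codes[, cols, drop = FALSE], 0L)
      dm <- res$d
      dimnames(dm) <- list(ids, ids)
      tr <- nj_tree(dm)
      tr <- root_tree(tr)
      for (cl in names(members)) {
        tipset <- members[[cl]]
        mono <- length(tipset) == 1L ||
          ape::is.monophyletic(tr, tipset)
        if (mono) hits[[cl]] <- hits[[cl]] + 1
      }
    }
  })
  support <- hits / n_boot
  assigned <- vapply(ids, function(id) {
    h <- hint[[id]]
    if (is.na(h) || !h %in% names(support)) return("UNASSIGNED")
    if (support[[h]] >= support_threshold) h else "UNASSIGNED"
  }, "")
  full <- nj_tree(pairwise_distances(msa))
  full <- root_tree(full)
  structure(list(
    assignments = data.frame(gene_id = ids, cluster_hint = unname(hint),
                             assigned = unname(assigned),
                             support = unname(ifelse(
                               is.na(hint) | !hint %in% names(support),
                               NA_real_, support[hint])),
                             stringsAsFactors = FALSE),
    support = support, n_boot = n_boot, tree = full
  ), class = "cluster_assignment")
}
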