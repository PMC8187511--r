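## ---- multiple sequence alignment container ------------------------------

#' Construct a labelled protein MSA
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (residues and `-`)
#' @param clusters optional named cluster labels (names = sequence ids);
#'   unlabelled rows get NA
#' @param reference_id id of the sequence whose ungapped 1-based positions
#'   define reference numbering
#' @return object of class `sreb_msa`
#' @export
sreb_msa <- function(seqs, clusters = NULL, reference_id = names(seqs)[1]) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences must all have equal length")
  if (!reference_id %in% names(seqs))
    stop("reference sequence not present in the alignment")
  cl <- stats::setNames(rep(NA_character_, length(seqs)), names(seqs))
  if (!is.null(clusters)) {
    common <- intersect(names(clusters), names(seqs))
    cl[common] <- unname(clusters[common])
  }
  structure(list(
    ids = names(seqs), seqs = seqs, clusters = cl,
    reference_id = reference_id, n_cols = nchar(seqs[[1]]),
    masked = rep(FALSE, nchar(seqs[[1]]))
  ), class = "sreb_msa")
}

#' @export
print.sreb_msa <- function(x, ...) {
  cat(sprintf("sreb_msa: %d sequences x %d columns (%d masked), reference %s\n",
              length(x$ids), x$n_cols, sum(x$masked), x$reference_id))
  invisible(x)
}

#' Reference position of every alignment column
#'
#' @param msa a `sreb_msa`
#' @return integer vector of length `n_cols`; NA where the reference is
#'   gapped
#' @export
ref_positions <- function(msa) {
  chars <- strsplit(msa$seqs[[msa$reference_id]], "")[[1]]
  pos <- cumsum(chars != "-")
  pos[chars == "-"] <- NA_integer_
  as.integer(pos)
}

## column index of a reference position (1-based)
ref_to_column <- function(msa, ref_pos) {
  rp <- ref_positions(msa)
  out <- match(ref_pos, rp)
  if (anyNA(out)) stop("reference position outside the alignment: ",
                       paste(ref_pos[is.na(out)], collapse = ", "))
  out
}

## ---- alignment ----------------------------------------------------------

.blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

.align_alphabet <- c(.amino_acids, "X")

## residue-frequency profile of a character matrix (gaps contribute 0)
.profile_of <- function(m) {
  K <- length(.align_alphabet)
  f <- matrix(0, K, ncol(m), dimnames = list(.align_alphabet, NULL))
  for (j in seq_len(ncol(m))) {
    tb <- table(factor(m[, j], levels = .align_alphabet))
    f[, j] <- as.numeric(tb) / nrow(m)
  }
  f
}

.merge_by_path <- function(ma, mb, path) {
  ncol_out <- length(path$a)
  out <- matrix("-", nrow(ma) + nrow(mb), ncol_out)
  out[seq_len(nrow(ma)), path$a != 0] <- ma[, path$a[path$a != 0], drop = FALSE]
  out[nrow(ma) + seq_len(nrow(mb)), path$b != 0] <-
    mb[, path$b[path$b != 0], drop = FALSE]
  rownames(out) <- c(rownames(ma), rownames(mb))
  out
}

#' Globally align two sequences or profiles
#'
#' Needleman-Wunsch/Gotoh global alignment with BLOSUM62 and affine gaps; a
#' gap of length L costs `gap_open + L * gap_ext`.
#'
#' @param a,b amino-acid strings, or character matrices of already-aligned
#'   blocks
#' @param gap_open,gap_ext affine gap parameters (positive penalties)
#' @return list with `alignment` (character matrix) and `score`
#' @export
align_pair <- function(a, b, gap_open = 10, gap_ext = 1) {
  to_mat <- function(x, tag) {
    if (is.matrix(x)) return(x)
    m <- matrix(strsplit(x, "")[[1]], nrow = 1)
    rownames(m) <- if (!is.null(names(x))) names(x) else tag
    m
  }
  ma <- to_mat(a, "a"); mb <- to_mat(b, "b")
  S <- .blosum62()[.align_alphabet, .align_alphabet]
  path <- profile_align_cpp(.profile_of(ma), .profile_of(mb), S,
                            gap_open, gap_ext)
  list(alignment = .merge_by_path(ma, mb, path), score = path$score)
}

#' Import or build a multiple protein alignment
#'
#' `mode = "import"` validates an existing equal-length alignment.
#' `mode = "progressive"` builds one: UPGMA guide tree on 3-mer distances,
#' then profile-profile Needleman-Wunsch merges with BLOSUM62 and affine
#' gaps (open 10, extend 1), deterministic throughout.
#'
#' @param proteins named character vector (aligned for import, unaligned
#'   for progressive)
#' @param mode `"import"` or `"progressive"`
#' @param clusters,reference_id passed to [sreb_msa()]
#' @param gap_open,gap_ext affine gap parameters for progressive mode
#' @param k k-mer size for the guide-tree distance
#' @return a `sreb_msa`
#' @export
align_or_import <- function(proteins, mode = c("import", "progressive"),
                            clusters = NULL,
                            reference_id = names(proteins)[1],
                            gap_open = 10, gap_ext = 1, k = 3L) {
  mode <- match.arg(mode)
  if (length(proteins) < 2L) stop("need at least two sequences")
  if (is.null(names(proteins)) || anyDuplicated(names(proteins)))
    stop("duplicate or missing sequence ids")
  if (mode == "import") {
    if (length(unique(nchar(proteins))) != 1L)
      stop("ragged import: aligned sequences differ in length")
    return(sreb_msa(proteins, clusters, reference_id))
  }
  n <- length(proteins)
  kmers <- lapply(proteins, function(s) {
    if (nchar(s) < k) return(character())
    unique(substring(s, seq_len(nchar(s) - k + 1L),
                     seq_len(nchar(s) - k + 1L) + k - 1L))
  })
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- length(intersect(kmers[[i]], kmers[[j]]))
    d[i, j] <- d[j, i] <- 1 - shared / max(1L, min(lengths(kmers)[c(i, j)]))
  }
  S <- .blosum62()[.align_alphabet, .align_alphabet]
  if (n == 2L) {
    blocks <- list()
    hc_merge <- matrix(c(-1L, -2L), 1)
  } else {
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    hc_merge <- hc$merge
    blocks <- list()
  }
  singleton <- function(i) {
    m <- matrix(strsplit(proteins[[i]], "")[[1]], nrow = 1)
    rownames(m) <- names(proteins)[i]
    m
  }
  for (step in seq_len(nrow(hc_merge))) {
    get <- function(idx) if (idx < 0) singleton(-idx) else blocks[[idx]]
    ma <- get(hc_merge[step, 1]); mb <- get(hc_merge[step, 2])
    path <- profile_align_cpp(.profile_of(ma), .profile_of(mb), S,
                              gap_open, gap_ext)
    blocks[[step]] <- .merge_by_path(ma, mb, path)
  }
  final <- blocks[[length(blocks)]]
  final <- final[names(proteins), , drop = FALSE]
  sreb_msa(stats::setNames(paste_rows(final), rownames(final)),
           clusters, reference_id)
}

#' Mask alignment columns before the reference's first transmembrane run
#'
#' N-terminal extracellular regions are highly variable and may contain
#' alternative start sites, so conservation statistics exclude all columns
#' strictly before the column holding the reference's TM1 start. Masked
#' columns stay in the matrix and are only flagged.
#'
#' @param msa a `sreb_msa`
#' @param tm either a named list of `tm_annotation` objects (from
#'   [predict_tm()]) or a [screen_genes()] data frame with a `tm1_start`
#'   column
#' @return the `sreb_msa` with its `masked` flags set
#' @export
mask_nterminal <- function(msa, tm) {
  rid <- msa$reference_id
  tm1 <- if (is.data.frame(tm)) {
    if (!rid %in% tm$gene_id) stop("reference lacks TM annotation")
    tm$tm1_start[match(rid, tm$gene_id)]
  } else {
    ann <- tm[[rid]]
    if (is.null(ann) || ann$count == 0L) stop("reference lacks TM annotation")
    ann$segments[1, "start"]
  }
  if (is.na(tm1)) stop("reference lacks TM annotation")
  col1 <- ref_to_column(msa, tm1)
  msa$masked <- seq_len(msa$n_cols) < col1
  msa
}

#' Drop sequences from an MSA
#' @param msa a `sreb_msa`
#' @param ids sequence ids to keep
#' @return a `sreb_msa` over `ids` (reference kept; masking preserved)
#' @export
subset_msa <- function(msa, ids) {
  if (!msa$reference_id %in% ids)
    stop("subset must retain the reference sequence")
  out <- sreb_msa(msa$seqs[ids], msa$clusters[ids], msa$reference_id)
  out$masked <- msa$masked
  out
}
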