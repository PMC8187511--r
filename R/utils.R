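#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1 at one decimal), the
#' convention used for all printed conservation percentages in this package.
#' Base R's `round()` rounds half to even and would print 96.25 as 96.2.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
#' @examples
#' round_half_up(96.25, 1)  # 96.3
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

## evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## split aligned sequences (equal length) into a character matrix, rows = ids
seq_matrix <- function(seqs, ids = names(seqs)) {
  stopifnot(length(unique(nchar(seqs))) == 1L)
  m <- do.call(rbind, strsplit(unname(as.character(seqs)), ""))
  rownames(m) <- ids
  m
}

paste_rows <- function(m) apply(m, 1L, paste, collapse = "")
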