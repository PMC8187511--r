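## ---- synthetic qPCR data generator --------------------------------------

#' Slope of an ideal standard curve at a given amplification efficiency
#'
#' A reaction with efficiency E multiplies template by (1+E) each cycle, so
#' Ct falls by 1/log10(1+E) per decade of input: slope = -1/log10(1+E)
#' (-3.3219 at 100 percent efficiency).
#'
#' @param efficiency amplification efficiency E in `[0, 1.1]` (1 = 100%)
#' @return slope in cycles per log10 quantity (negative)
#' @export
efficiency_to_slope <- function(efficiency) -1 / log10(1 + efficiency)

#' Simulate qPCR Ct tables and dilution series with planted fold changes
#'
#' Ct values follow `intercept + slope * log10(quantity) + N(0, ct_sd)` with
#' the slope implied by each gene's configured efficiency. Planted fold
#' changes are encoded in the starting quantities of each sample group;
#' every sample is assayed in duplicate wells and each gene gets a
#' triplicate relative standard curve spanning `dilution_points` ten-fold
#' points.
#'
#' @param config a [sim_config()] object (the `qpcr` element is used)
#' @return list with `ct_table` (sample_id, group, gene, replicate, ct,
#'   input_rna_ug), `curves_input` (gene, quantity, replicate, ct) and
#'   `truth` (fold changes, efficiencies, slopes, intercepts)
#' @export
simulate_ct <- function(config) {
  q <- config$qpcr
  slopes <- efficiency_to_slope(q$efficiency)
  for (g in q$genes) {
    fc <- q$planted_fold_changes[[g]]
    if (is.null(fc)) stop("no planted fold change for gene ", g)
    if (any(fc <= 0) || q$base_quantity[[g]] <= 0)
      stop("non-positive quantities are not allowed")
  }
  with_seed(config$seed, {
    rows <- list()
    for (grp in q$groups) {
      for (i in seq_len(q$n_per_group[[grp]])) {
        sid <- sprintf("%s_%02d", grp, i)
        for (g in q$genes) {
          quant <- q$base_quantity[[g]] * q$planted_fold_changes[[g]][[grp]]
          for (r in seq_len(q$n_well_replicates)) {
            ct <- q$intercept[[g]] + slopes[[g]] * log10(quant) +
              stats::rnorm(1L, 0, q$ct_sd)
            rows[[length(rows) + 1L]] <- data.frame(
              sample_id = sid, group = grp, gene = g, replicate = r,
              ct = ct, input_rna_ug = q$input_rna_ug,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    ct_table <- do.call(rbind, rows)

    dil <- q$dilution_factor^-(seq_len(q$dilution_points) - 1L)
    crows <- list()
    for (g in q$genes) {
      for (d in dil) {
        for (r in seq_len(q$n_curve_replicates)) {
          ct <- q$intercept[[g]] + slopes[[g]] * log10(d) +
            stats::rnorm(1L, 0, q$ct_sd)
          crows[[length(crows) + 1L]] <- data.frame(
            gene = g, quantity = d, replicate = r, ct = ct,
            stringsAsFactors = FALSE)
        }
      }
    }
    curves_input <- do.call(rbind, crows)

    list(ct_table = ct_table, curves_input = curves_input,
         truth = list(fold_changes = q$planted_fold_changes,
                      efficiency = q$efficiency, slope = slopes,
                      intercept = q$intercept,
                      calibrator = q$calibrator))
  })
}
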