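## ---- qPCR relative quantification ---------------------------------------

#' Fit a relative standard curve and derive amplification efficiency
#'
#' Ordinary least squares of Ct on log10 relative quantity over all pooled
#' replicate points. Efficiency E = 10^(-1/slope) - 1; the QC flag accepts
#' roughly 90-100% efficiency (window widened by `tol` on both sides).
#'
#' @param dilutions data frame with columns `quantity` (relative, positive)
#'   and `ct`; replicate rows are pooled into one fit
#' @param gene optional gene label carried through
#' @param qc_window efficiency window considered optimal
#' @param tol slack applied to both window edges ("approximately 90-100%")
#' @return object of class `standard_curve`: `gene`, `points` (log10
#'   quantity vs mean ct), `slope`, `intercept`, `r_squared`, `efficiency`,
#'   `qc_pass`, `monotone`
#' @export
fit_standard_curve <- function(dilutions, gene = NA_character_,
                               qc_window = c(0.90, 1.00), tol = 0.02) {
  if (any(dilutions$quantity <= 0)) stop("quantities must be positive")
  qs <- sort(unique(dilutions$quantity), decreasing = TRUE)
  if (length(qs) < 4L) stop("a standard curve needs at least 4 distinct points")
  lq <- log10(dilutions$quantity)
  fit <- stats::lm(ct ~ lq, data = data.frame(ct = dilutions$ct, lq = lq))
  slope <- unname(stats::coef(fit)[2]); intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope >= 0)
    warning("standard curve slope is not negative; efficiency undefined")
  mean_ct <- vapply(qs, function(q)
    mean(dilutions$ct[dilutions$quantity == q]), 0)
  monotone <- !is.unsorted(mean_ct)     # ct rises as quantity falls
  if (!monotone) warning("mean Ct is not monotone along the dilution series")
  eff <- 10^(-1 / slope) - 1
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((dilutions$ct - mean(dilutions$ct))^2)
  structure(list(
    gene = gene, points = data.frame(log10_quantity = log10(qs),
                                     mean_ct = mean_ct),
    slope = slope, intercept = intercept, r_squared = r2, efficiency = eff,
    qc_pass = eff >= qc_window[1] - tol && eff <= qc_window[2] + tol,
    monotone = monotone), class = "standard_curve")
}

#' Fit standard curves for every gene in a dilution table
#' @param curves_input data frame with gene, quantity, ct (replicates pooled)
#' @param ... passed to [fit_standard_curve()]
#' @return named list of `standard_curve` objects
#' @export
fit_standard_curves <- function(curves_input, ...) {
  genes <- unique(curves_input$gene)
  out <- lapply(genes, function(g)
    fit_standard_curve(curves_input[curves_input$gene == g, , drop = FALSE],
                       gene = g, ...))
  stats::setNames(out, genes)
}

## interpolate starting quantity from a curve
.quantity_from_ct <- function(ct, curve) 10^((ct - curve$intercept) / curve$slope)

#' Relative expression from Ct values under three normalization modes
#'
#' Well replicates are averaged per sample and gene, quantities are
#' interpolated from each gene's standard curve, normalized according to
#' `mode`, and finally expressed relative to the calibrator group (whose
#' mean becomes 1.0):
#' \describe{
#'   \item{ref_gene}{target quantity divided by the reference gene's
#'     quantity in the same sample}
#'   \item{fixed_input}{quantity used directly; all samples must share the
#'     same RNA input}
#'   \item{per_ug_input}{quantity divided by the sample's RNA input in
#'     micrograms}
#' }
#' Samples with missing Ct (non-detects) propagate NA and are excluded
#' from calibrator means.
#'
#' @param ct_table data frame: sample_id, group, gene, replicate, ct,
#'   input_rna_ug
#' @param curves named list of `standard_curve` objects (one per gene)
#' @param mode one of ref_gene, fixed_input, per_ug_input
#' @param ref_gene reference gene name (ref_gene mode)
#' @param calibrator group whose mean expression defines 1.0
#' @return data frame of class `rel_expression`: sample_id, group, gene,
#'   raw (normalized quantity before calibration), value, mode, calibrator
#' @export
quantify <- function(ct_table, curves, mode = c("ref_gene", "fixed_input",
                                                "per_ug_input"),
                     ref_gene = NULL, calibrator) {
  mode <- match.arg(mode)
  if (!calibrator %in% ct_table$group) stop("calibrator group not present")
  if (!"input_rna_ug" %in% names(ct_table)) ct_table$input_rna_ug <- NA_real_
  agg <- stats::aggregate(ct ~ sample_id + gene, data = ct_table, FUN = mean)
  meta <- unique(ct_table[, c("sample_id", "group", "input_rna_ug")])
  agg$group <- meta$group[match(agg$sample_id, meta$sample_id)]
  agg$input_rna_ug <- meta$input_rna_ug[match(agg$sample_id, meta$sample_id)]
  agg$quantity <- vapply(seq_len(nrow(agg)), function(i) {
    cv <- curves[[agg$gene[i]]]
    if (is.null(cv)) stop("no standard curve for gene ", agg$gene[i])
    .quantity_from_ct(agg$ct[i], cv)
  }, 0)
  if (mode == "ref_gene") {
    if (is.null(ref_gene)) stop("ref_gene mode needs a reference gene")
    refs <- agg[agg$gene == ref_gene, c("sample_id", "quantity")]
    if (!nrow(refs)) stop("missing reference gene: ", ref_gene)
    agg <- agg[agg$gene != ref_gene, , drop = FALSE]
    rq <- refs$quantity[match(agg$sample_id, refs$sample_id)]
    if (anyNA(rq)) stop("missing reference gene for sample(s): ",
                        paste(unique(agg$sample_id[is.na(rq)]), collapse = ", "))
    agg$raw <- agg$quantity / rq
  } else if (mode == "fixed_input") {
    if (length(unique(agg$input_rna_ug)) != 1L)
      stop("fixed_input mode requires equal RNA input across samples")
    agg$raw <- agg$quantity
  } else {
    if (anyNA(agg$input_rna_ug)) stop("per_ug_input mode needs input_rna_ug")
    agg$raw <- agg$quantity / agg$input_rna_ug
  }
  out <- lapply(split(agg, agg$gene), function(gg) {
    cal <- mean(gg$raw[gg$group == calibrator], na.rm = TRUE)
    gg$value <- gg$raw / cal
    gg
  })
  res <- do.call(rbind, out)
  res <- res[order(match(res$sample_id, unique(ct_table$sample_id)),
                   res$gene), c("sample_id", "group", "gene", "raw", "value")]
  res$mode <- mode
  res$calibrator <- calibrator
  rownames(res) <- NULL
  class(res) <- c("rel_expression", "data.frame")
  res
}

#' Screen candidate reference genes for stability across groups
#'
#' One-way ANOVA of log-transformed interpolated quantities across groups;
#' a candidate with p < alpha is unstable and should not be used for
#' ref_gene normalization.
#'
#' @param ct_table data frame as in [quantify()]
#' @param candidates candidate reference gene names
#' @param curves named list of `standard_curve` objects
#' @param alpha significance level
#' @return data frame: gene, p_value, stable
#' @export
reference_gene_screen <- function(ct_table, candidates, curves,
                                  alpha = 0.05) {
  if (length(unique(ct_table$group)) < 2L)
    stop("reference screening needs at least two groups")
  rows <- lapply(candidates, function(g) {
    sub <- ct_table[ct_table$gene == g, , drop = FALSE]
    if (!nrow(sub)) stop("candidate gene absent from Ct table: ", g)
    agg <- stats::aggregate(ct ~ sample_id + group, data = sub, FUN = mean)
    q <- log(.quantity_from_ct(agg$ct, curves[[g]]))
    p <- summary(stats::aov(q ~ factor(agg$group)))[[1]][["Pr(>F)"]][1]
    data.frame(gene = g, p_value = p, stable = p >= alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## compact letter display by insert-and-absorb on a pairwise p matrix
cld_letters <- function(groups, pmat, alpha = 0.05) {
  sets <- list(groups)
  for (i in seq_along(groups)[-length(groups)]) {
    for (j in (i + 1):length(groups)) {
      if (is.na(pmat[i, j]) || pmat[i, j] >= alpha) next
      a <- groups[i]; b <- groups[j]
      new_sets <- list()
      for (s in sets) {
        if (a %in% s && b %in% s)
          new_sets <- c(new_sets, list(setdiff(s, a), setdiff(s, b)))
        else new_sets <- c(new_sets, list(s))
      }
      ## absorb subsets
      keep <- rep(TRUE, length(new_sets))
      for (u in seq_along(new_sets)) for (v in seq_along(new_sets)) {
        if (u != v && keep[u] && keep[v] &&
            all(new_sets[[u]] %in% new_sets[[v]]) &&
            (length(new_sets[[u]]) < length(new_sets[[v]]) || u > v))
          keep[u] <- FALSE
      }
      sets <- new_sets[keep]
    }
  }
  sets <- sets[order(vapply(sets, function(s) min(match(s, groups)), 0L))]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (k in seq_along(sets))
    for (g in sets[[k]]) out[g] <- paste0(out[g], letters[k])
  out
}

#' Group comparisons of relative expression
#'
#' Natural-log-transforms the values, then compares groups with a Welch
#' two-sample t-test (2 groups) or a one-way ANOVA with Tukey HSD post-hoc
#' tests (more than 2), summarised as a compact letter display: groups
#' sharing a letter do not differ at `alpha`.
#'
#' @param values a `rel_expression` data frame (or compatible: gene, group,
#'   value)
#' @param alpha significance level
#' @return list of class `group_stats` with `summary` (gene, group, n,
#'   mean, se, letters), `tests` (gene, test, p_value) and `pairwise`
#'   (named list of pairwise p-value matrices, ANOVA case only)
#' @export
group_tests <- function(values, alpha = 0.05) {
  vals <- values[!is.na(values$value), , drop = FALSE]
  if (any(vals$value <= 0)) stop("relative expression must be positive before log transform")
  summaries <- list(); tests <- list(); pairwise <- list()
  for (g in unique(vals$gene)) {
    gg <- vals[vals$gene == g, , drop = FALSE]
    groups <- unique(gg$group)
    tab <- table(gg$group)
    if (length(groups) < 2L || any(tab < 2L))
      stop("each gene needs >= 2 groups with >= 2 samples (gene ", g, ")")
    lg <- log(gg$value)
    if (length(groups) == 2L) {
      tt <- stats::t.test(lg ~ factor(gg$group))
      p <- tt$p.value
      lets <- if (p < alpha) stats::setNames(c("a", "b"), groups)
      else stats::setNames(c("a", "a"), groups)
      tests[[g]] <- data.frame(gene = g, test = "t_test", p_value = p)
    } else {
      fit <- stats::aov(lg ~ grp, data = data.frame(lg = lg,
                                                    grp = factor(gg$group)))
      p <- summary(fit)[[1]][["Pr(>F)"]][1]
      tuk <- stats::TukeyHSD(fit)$grp
      pmat <- matrix(NA_real_, length(groups), length(groups),
                     dimnames = list(groups, groups))
      for (r in rownames(tuk)) {
        pair <- strsplit(r, "-", fixed = TRUE)[[1]]
        pmat[pair[1], pair[2]] <- pmat[pair[2], pair[1]] <- tuk[r, "p adj"]
      }
      lets <- cld_letters(groups, pmat, alpha)
      pairwise[[g]] <- pmat
      tests[[g]] <- data.frame(gene = g, test = "anova", p_value = p)
    }
    summaries[[g]] <- do.call(rbind, lapply(groups, function(grp) {
      v <- gg$value[gg$group == grp]
      data.frame(gene = g, group = grp, n = length(v), mean = mean(v),
                 se = stats::sd(v) / sqrt(length(v)),
                 letters = unname(lets[grp]), stringsAsFactors = FALSE)
    }))
  }
  structure(list(summary = do.call(rbind, c(summaries, make.row.names = FALSE)),
                 tests = do.call(rbind, c(tests, make.row.names = FALSE)),
                 pairwise = pairwise, alpha = alpha),
            class = "group_stats")
}
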