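test_that("standard-curve efficiency follows the closed forms", {
  mk_series <- function(slope, intercept = 24, points = 5) {
    q <- 10^-(seq_len(points) - 1L)
    data.frame(quantity = rep(q, each = 2),
               ct = intercept + slope * log10(rep(q, each = 2)))
  }
  ## -3.3219 cycles per decade is exactly 100% efficiency
  c100 <- fit_standard_curve(mk_series(-1 / log10(2)))
  expect_equal(round(100 * c100$efficiency, 1), 100.0)
  expect_true(c100$qc_pass)
  expect_equal(c100$r_squared, 1, tolerance = 1e-12)
  ## -3.5885 corresponds to about 90%
  c90 <- fit_standard_curve(mk_series(-3.5885))
  expect_equal(round(100 * c90$efficiency, 1), 90.0, tolerance = 0.1)
  expect_true(c90$qc_pass)
  ## outside the QC window
  c80 <- fit_standard_curve(mk_series(efficiency_to_slope(0.8)))
  expect_false(c80$qc_pass)
  ## fewer than 4 distinct quantities is an error
  expect_error(fit_standard_curve(data.frame(quantity = c(1, .1, .01),
                                             ct = c(20, 23, 26))), "at least 4")
  expect_error(fit_standard_curve(data.frame(quantity = c(1, .1, .01, 0),
                                             ct = c(20, 23, 26, 29))), "positive")
  ## non-monotone series draws a QC warning
  expect_warning(fit_standard_curve(
    data.frame(quantity = 10^-(0:4), ct = c(20, 23, 22, 29, 32))), "monotone")
})

test_that("noiseless planted fold changes are recovered exactly in all modes", {
  cfg <- small_config(seed = 81)
  cfg$qpcr$ct_sd <- 0
  sim <- simulate_ct(cfg)
  curves <- fit_standard_curves(sim$curves_input)
  truth <- sim$truth$fold_changes

  check_mode <- function(mode, ...) {
    re <- quantify(sim$ct_table, curves, mode, calibrator = "TS", ...)
    for (g in unique(re$gene)) {
      for (grp in c("TS", "OVV")) {
        v <- mean(re$value[re$gene == g & re$group == grp])
        expect_equal(v, unname(truth[[g]][grp]), tolerance = 1e-9,
                     label = paste(mode, g, grp))
      }
    }
    re
  }
  check_mode("ref_gene", ref_gene = "r18s")
  fixed <- check_mode("fixed_input")
  perug <- check_mode("per_ug_input")
  ## with constant 2.5 ug input the two curve-based modes differ only by
  ## that factor before calibration
  expect_equal(fixed$raw / perug$raw, rep(2.5, nrow(fixed)), tolerance = 1e-9)
  ## and the calibrator group means exactly 1
  expect_equal(mean(fixed$value[fixed$group == "TS" & fixed$gene == "sreb1"]),
               1, tolerance = 1e-12)
})

test_that("quantification modes enforce their preconditions", {
  cfg <- small_config(seed = 82)
  cfg$qpcr$ct_sd <- 0
  sim <- simulate_ct(cfg)
  curves <- fit_standard_curves(sim$curves_input)
  expect_error(quantify(sim$ct_table, curves, "ref_gene", calibrator = "TS"),
               "reference gene")
  uneven <- sim$ct_table
  uneven$input_rna_ug[1:4] <- 1.0
  expect_error(quantify(uneven, curves, "fixed_input", calibrator = "TS"),
               "equal RNA input")
  ## per-microgram mode: doubling the input halves the value
  doubled <- sim$ct_table
  doubled$input_rna_ug <- ifelse(doubled$group == "OVV", 5.0, 2.5)
  re <- quantify(doubled, curves, "per_ug_input", calibrator = "TS")
  base <- quantify(sim$ct_table, curves, "per_ug_input", calibrator = "TS")
  ratio <- re$raw[re$group == "OVV"] / base$raw[base$group == "OVV"]
  expect_equal(ratio, rep(0.5, length(ratio)), tolerance = 1e-9)
  expect_error(quantify(sim$ct_table, curves, "ref_gene", ref_gene = "r18s",
                        calibrator = "XX"), "calibrator")
})

test_that("ref_gene values are invariant to a global quantity rescaling", {
  cfg <- small_config(seed = 83)
  cfg$qpcr$ct_sd <- 0
  sim <- simulate_ct(cfg)
  curves <- fit_standard_curves(sim$curves_input)
  re <- quantify(sim$ct_table, curves, "ref_gene", ref_gene = "r18s",
                 calibrator = "TS")
  ## multiply every starting quantity by 50: every Ct shifts by
  ## slope * log10(50) for its gene
  shifted <- sim$ct_table
  for (g in unique(shifted$gene)) {
    idx <- shifted$gene == g
    shifted$ct[idx] <- shifted$ct[idx] + curves[[g]]$slope * log10(50)
  }
  re2 <- quantify(shifted, curves, "ref_gene", ref_gene = "r18s",
                  calibrator = "TS")
  expect_equal(re2$value, re$value, tolerance = 1e-9)
})

test_that("reference screening finds the planted unstable candidate", {
  cfg <- small_config(seed = 84)
  cfg$qpcr$ct_sd <- 0.1
  sim <- simulate_ct(cfg)
  curves <- fit_standard_curves(sim$curves_input)
  scr <- reference_gene_screen(sim$ct_table, c("r18s", "gapdh"), curves)
  expect_true(scr$stable[scr$gene == "r18s"])
  expect_false(scr$stable[scr$gene == "gapdh"])   # planted 5-fold shift
  one_group <- sim$ct_table[sim$ct_table$group == "TS", ]
  expect_error(reference_gene_screen(one_group, "r18s", curves), "two groups")
})

test_that("group tests separate planted differences and letter the groups", {
  cfg <- small_config(seed = 85)
  cfg$qpcr$ct_sd <- 0.2
  cfg$qpcr$groups <- c("TS", "OVV", "OVP")
  cfg$qpcr$n_per_group <- c(TS = 8L, OVV = 8L, OVP = 8L)
  cfg$qpcr$planted_fold_changes <- list(
    sreb1 = c(TS = 1, OVV = 8, OVP = 1),   # one shifted group
    sreb2 = c(TS = 1, OVV = 1, OVP = 1),   # null gene
    sreb3a = c(TS = 1, OVV = 4, OVP = 4),
    smim20 = c(TS = 1, OVV = 1, OVP = 1),
    r18s = c(TS = 1, OVV = 1, OVP = 1),
    gapdh = c(TS = 1, OVV = 1, OVP = 1))
  sim <- simulate_ct(cfg)
  curves <- fit_standard_curves(sim$curves_input)
  re <- quantify(sim$ct_table, curves, "ref_gene", ref_gene = "r18s",
                 calibrator = "TS")
  gs <- group_tests(re)
  sum1 <- gs$summary[gs$summary$gene == "sreb1", ]
  expect_equal(gs$tests$test[gs$tests$gene == "sreb1"], "anova")
  expect_lt(gs$tests$p_value[gs$tests$gene == "sreb1"], 0.05)
  ## the shifted group gets its own letter
  expect_false(sum1$letters[sum1$group == "OVV"] %in%
                 sum1$letters[sum1$group != "OVV"])
  ## letters are a valid compact letter display of the pairwise tests
  pm <- gs$pairwise[["sreb1"]]
  lets <- stats::setNames(sum1$letters, sum1$group)
  for (g1 in rownames(pm)) for (g2 in colnames(pm)) {
    if (g1 == g2) next
    share <- any(strsplit(lets[g1], "")[[1]] %in% strsplit(lets[g2], "")[[1]])
    expect_equal(share, pm[g1, g2] >= 0.05, label = paste(g1, g2))
  }
})

test_that("two identical groups are not separated", {
  cfg <- small_config(seed = 86)
  cfg$qpcr$ct_sd <- 0.2
  sim <- simulate_ct(cfg)
  curves <- fit_standard_curves(sim$curves_input)
  re <- quantify(sim$ct_table, curves, "ref_gene", ref_gene = "r18s",
                 calibrator = "TS")
  gs <- group_tests(re[re$gene == "smim20", ])
  ## smim20 planted at 8-fold: clearly separated
  expect_lt(gs$tests$p_value[gs$tests$gene == "smim20"], 0.05)
  sm <- gs$summary[gs$summary$gene == "smim20", ]
  expect_false(sm$letters[1] == sm$letters[2])
  ## a null gene shares one letter
  re2 <- re[re$gene == "sreb2", ]
  re2$value <- rep(re2$value[re2$group == "TS"], 2)[seq_len(nrow(re2))]
  gs2 <- group_tests(re2)
  s2 <- gs2$summary
  expect_true(s2$letters[1] == s2$letters[2])
  expect_error(group_tests(transform(re2, value = -value)), "positive")
})
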