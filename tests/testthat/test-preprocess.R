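# Fold-change arithmetic, outlier screening, Dunnett testing, inclusion
# filters.

test_that("delta-delta-Ct fold changes follow the hand arithmetic", {
  ct <- data.frame(gene = "G", treatment = "T",
                   rel_conc = c(0, 0, 0.1, 0.1),
                   replicate = c(1, 2, 1, 2),
                   ct_target = c(25, 25, 24, 24),
                   ct_reference = c(20, 20, 20, 20))
  fc <- fold_change_from_ct(ct)
  # treated dCt one cycle below the vehicle mean dCt: log2FC = +1
  expect_equal(fc$log2fc, c(0, 0, 1, 1))
  # all wells identical: log2FC 0 everywhere
  ct0 <- ct; ct0$ct_target <- 25
  expect_equal(fold_change_from_ct(ct0)$log2fc, rep(0, 4))
  # per-well constant added to both target and reference cancels
  ct1 <- ct
  shift <- c(0.3, -0.2, 1.1, 0.6)
  ct1$ct_target <- ct1$ct_target + shift
  ct1$ct_reference <- ct1$ct_reference + shift
  expect_equal(fold_change_from_ct(ct1)$log2fc, fc$log2fc,
               tolerance = 1e-12)
  # missing vehicle errors with the offending batch named
  expect_error(fold_change_from_ct(ct[ct$rel_conc > 0, ]),
               "no vehicle.*gene 'G'")
  ctbad <- ct; ctbad$ct_target[1] <- -1
  expect_error(fold_change_from_ct(ctbad), "finite and positive")
})

test_that("outlier screening drops only flagged records and logs them", {
  tab <- response_table(list("0" = c(0.1, 0.0, -0.1, 25.0)))
  # IQR fences at k = 1.5: upper fence 6.325 + 1.5 * 6.35, so 25 is removed
  res <- remove_outliers(tab, "iqr", k = 1.5)
  expect_equal(nrow(res$table), 3)
  expect_false(25 %in% res$table$log2fc)
  expect_equal(res$log$log2fc, 25)
  expect_match(res$log$reason, "iqr")
  # grubbs flags the same gross outlier
  resg <- remove_outliers(tab, "grubbs", alpha = 0.05)
  expect_false(25 %in% resg$table$log2fc)
  # method none is the identity with an empty log
  resn <- remove_outliers(tab, "none")
  expect_identical(resn$table, tab)
  expect_equal(nrow(resn$log), 0)
  # equal values are never flagged
  expect_equal(nrow(remove_outliers(
    response_table(list("0" = rep(0.5, 5))), "iqr")$log), 0)
  # cells under 3 observations are skipped and logged, not screened
  small <- response_table(list("0.1" = c(0, 100)))
  ress <- remove_outliers(small, "grubbs")
  expect_equal(nrow(ress$table), 2)
  expect_match(ress$log$reason, "cell size")
})

test_that("Dunnett testing flags shifted groups and handles exact ties", {
  tab <- response_table(list("0" = rep(0.5, 4), "0.01" = rep(0.5, 4),
                             "0.1" = rep(0.5, 4)))
  expect_warning(res <- dunnett_vs_control(tab, "G", "T"),
                 "zero residual variance")
  expect_equal(res$p_adj, c(1, 1))
  expect_false(any(res$significant))
  # a 10-SD shift is overwhelmingly significant
  set.seed(31)
  tab2 <- response_table(list("0" = rnorm(4), "0.01" = rnorm(4),
                              "0.05" = rnorm(4), "0.1" = rnorm(4) + 10))
  res2 <- dunnett_vs_control(tab2, "G", "T")
  expect_lt(res2$p_adj[res2$rel_conc == 0.1], 1e-6)
  expect_true(res2$significant[res2$rel_conc == 0.1])
  # family-wise adjustment can only increase the per-contrast p-value
  for (cc in c(0.01, 0.05)) {
    x <- tab2$log2fc[tab2$rel_conc == cc]
    v <- tab2$log2fc[tab2$rel_conc == 0]
    raw <- t.test(x, v, var.equal = TRUE)$p.value
    expect_gte(res2$p_adj[res2$rel_conc == cc] + 1e-9, raw)
  }
  # preconditions
  expect_error(dunnett_vs_control(tab2[tab2$rel_conc > 0, ], "G", "T"),
               "no vehicle")
  one <- response_table(list("0" = rnorm(4), "0.1" = rnorm(4)))
  expect_error(dunnett_vs_control(one, "G", "T"), "two non-vehicle")
})

test_that("treatment filter enforces the minimum-observation rule", {
  tab <- rbind(response_table(list("0" = c(0, 0.1, -0.1), "0.1" = c(1, 1.2)),
                              treatment = "A"),
               response_table(list("0" = c(0, 0.1, -0.1), "0.1" = 2.0),
                              treatment = "B"))
  res <- filter_treatments(tab, min_obs = 2)
  # a cell with exactly min_obs observations is retained (boundary inclusive)
  expect_true(any(res$table$treatment == "A" & res$table$rel_conc == 0.1))
  # a cell with a single surviving replicate is removed and logged
  expect_false(any(res$table$treatment == "B" & res$table$rel_conc == 0.1))
  expect_identical(res$log$treatment, "B")
  expect_equal(res$log$n_obs, 1L)
  # min_obs 1 keeps everything; filtering is idempotent
  expect_identical(filter_treatments(tab, 1)$table, tab)
  again <- filter_treatments(res$table, 2)
  expect_identical(again$table, res$table)
  expect_equal(nrow(again$log), 0)
})

test_that("gene selection applies the significant-component rule", {
  pat <- significance_pattern_fixture()
  pat$rel_conc <- 0.1  # any-concentration flag expressed as one record
  genes <- select_genes_for_ia(pat, min_components = 3)
  expect_setequal(as.character(genes),
                  c("ALDH3A1", "CYP1A1", "CYP1B1", "GSTA", "HMOX1", "NQO1"))
  counts <- attr(genes, "counts")
  expect_equal(unname(counts[["TJP2"]]), 2)   # two components: excluded
  expect_equal(unname(counts[["GJA1"]]), 0)   # no components: excluded
  # the mixture treatment is never counted
  with_mix <- rbind(pat, data.frame(gene = "TJP2", treatment = "ToxMix",
                                    significant = TRUE, rel_conc = 0.1))
  genes2 <- select_genes_for_ia(with_mix, 3, exclude_treatments = "ToxMix")
  expect_false("TJP2" %in% genes2)
  # selection is idempotent in the sense that re-filtering the selected
  # genes' records returns the same set
  sub <- pat[pat$gene %in% genes, ]
  expect_setequal(as.character(select_genes_for_ia(sub, 3)),
                  as.character(genes))
})

test_that("significance_table covers every batch once", {
  s <- study_sim(seed = 21, genes = "CYP1A1", noise_sd = 0.25)
  tab <- rbind(generate_component_responses(s$cfg, s$truth),
               generate_mixture_response(s$cfg, s$truth))
  sig <- suppressWarnings(significance_table(tab))
  expect_equal(nrow(sig),
               length(unique(tab$treatment)) * length(s$cfg$rel_concs))
  expect_true(all(sig$p_adj >= 0 & sig$p_adj <= 1))
  expect_identical(sig$significant, sig$p_adj < 0.05)
})
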