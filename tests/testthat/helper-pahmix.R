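# Shared builders for the test suite. Everything is constructed in code;
# the only file fixtures are the bundled mixture/pattern tables.

toxmix <- function(total = 100) pah_mixture("ToxMix", total)

# two-component mixture with exact proportions (no renormalization effects)
two_comp_mix <- function(p1 = 0.5, tef1 = 1, tef2 = 1, total = 100,
                         name = "mix2") {
  mixture_definition(name, data.frame(
    component = c("A", "B"),
    proportion_percent = c(p1, 1 - p1) * 100,
    tef = c(tef1, tef2)), full_strength_total = total)
}

# constant-response curve (linear with zero slope): effect E at every dose
const_curve <- function(E, gene = "G", treatment = "T") {
  dr_curve("linear", c(b0 = E, b1 = 0), gene = gene, treatment = treatment,
           direction = if (E >= 0.1) "up" else if (E <= -0.1) "down"
                       else "flat")
}

# an n-component equal-proportion mixture plus constant component curves,
# for hand-checkable IA contexts (all TEFs 1)
const_ia_context <- function(effects, dose_range = c(0.1, 10)) {
  n <- length(effects)
  mix <- mixture_definition("cmix", data.frame(
    component = paste0("C", seq_len(n)),
    proportion_percent = rep(100 / n, n),
    tef = rep(1, n)), full_strength_total = 100)
  curves <- stats::setNames(
    lapply(seq_len(n), function(i) const_curve(effects[i])),
    paste0("C", seq_len(n)))
  build_context("G", curves, mix, axis = "uM", dose_range = dose_range)
}

# study-conditions simulation over a subset of genes
study_sim <- function(seed, genes = NULL, noise_sd = 0,
                      interaction = "additive", ...) {
  mix <- toxmix()
  truth <- study_truth(mix, genes = genes)
  if (is.null(genes)) genes <- unique(significance_pattern_fixture()$gene)
  cfg <- simulation_config(mix, genes, noise_sd = noise_sd,
                           interaction = interaction, seed = seed, ...)
  list(mix = mix, truth = truth, cfg = cfg)
}

# small hand-built response table: one gene x treatment, vehicle + dose
# groups with given per-group values
response_table <- function(values_by_conc, gene = "G", treatment = "T") {
  do.call(rbind, lapply(names(values_by_conc), function(cc) {
    v <- values_by_conc[[cc]]
    data.frame(gene = gene, treatment = treatment,
               rel_conc = as.numeric(cc), replicate = seq_along(v),
               log2fc = v, stringsAsFactors = FALSE)
  }))
}
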