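# pahmix

Component-based additivity analysis for chemical mixtures, built around
transcriptional (qPCR log2 fold-change) dose–response data from polycyclic
aromatic hydrocarbon (PAH) mixture studies. The package is for
toxicologists and risk assessors who have (or want to simulate) per-gene
responses to a defined mixture and to each of its components, and who want
to ask a quantitative question: *does the mixture behave as the additive
combination of its parts?*

## What it computes

The additivity model is **independent action** (IA, response addition),
modified to handle genes whose components split between up- and
down-regulation. For a gene, each component *i* contributes its fitted
dose–response effect `E_i(c_i)` at its dose within the mixture; with
normalized effects `u_i = E_i / E_max` per direction (clamped to [0, 1]):

```
log2FC_mix(c) = (1 - prod_i (1 - u_i)) * max_up
              + (1 - prod_j (1 - v_j)) * max_down
```

evaluated either on the micromolar axis (component *i* at
`proportion_i * c_mix`) or on the **BeP-equivalent axis**, where component
concentrations are scaled by toxic equivalency factors (TEFs) onto the
benzo[e]pyrene reference scale while retaining each component's own
response curve.

Around that core the package provides:

* **Mixture objects** (`mixture_definition()`, bundled `pah_mixture()`
  fixtures for the seven-PAH ToxMix with TEFs and the six-PAH AbundMix)
  with all concentration-axis arithmetic (`component_dose()`,
  `bep_equivalent()`, `component_axis_transform()`).
* **Preprocessing**: comparative ΔΔCt fold changes
  (`fold_change_from_ct()`), optional IQR/Grubbs outlier screening with an
  audit log (`remove_outliers()`), one-way ANOVA + Dunnett many-to-one
  testing against vehicle (`dunnett_vs_control()`), and the inclusion
  filters (≥2 valid observations per treatment cell, ≥3 significant
  components per gene; `filter_treatments()`, `select_genes_for_ia()`).
* **Dose–response fitting** (`fit_family()`, `fit_all_families()`):
  log-logistic (2–4p), Weibull types 1/2, Michaelis–Menten, asymptotic
  regression, Gompertz, linear and quadratic; AIC model selection with the
  rule that a polynomial must win by more than 2 AIC units
  (`select_model()`); closed-form relative EC50s (`ec50()`).
* **IA prediction** (`build_context()`, `ia_predict()`) and **evaluation**
  against the observed mixture: Pearson r between fitted curves on a
  log-spaced grid, RMSE against per-dose means, and the conventional
  weak/moderate/strong and small/moderate/large bands (`categorize()`).
* A **synthetic-data generator** with known ground truth
  (`simulation_config()`, `study_truth()`, `generate_component_responses()`,
  `generate_mixture_response()`, `generate_ct_table()`), including
  controllable synergy/antagonism, so the whole pipeline is verifiable.
* A one-call **pipeline** (`pipeline_config()`, `run_pipeline()`) with
  deterministic seeding, per-stage exclusion logs and a JSON manifest.

## A worked example

Simulate the canonical study conditions (seven-component ToxMix, nine
biomarker genes, 4 replicates at 0.5/1/5/10% relative concentration, noise
SD 0.3 log2 units), then run the full analysis:

```r
library(pahmix)
mix   <- pah_mixture("ToxMix")
truth <- study_truth(mix)
cfg   <- simulation_config(mix, genes = unique(significance_pattern_fixture()$gene),
                           noise_sd = 0.3, seed = 17)
pc  <- pipeline_config(mix, list(mode = "simulate", truth = truth, sim = cfg))
res <- run_pipeline(pc)
res$genes
#> [1] "ALDH3A1" "CYP1A1"  "CYP1B1"  "GSTA"    "HMOX1"   "NQO1"
res$evaluation
#>       gene axis pearson_r   rmse     r_category rmse_category
#> 1  ALDH3A1   uM     0.999 0.1368         strong         small
#> 2  ALDH3A1  bep     0.958 0.3934         strong         small
#> 3   CYP1A1   uM     0.931 0.1951         strong         small
#> 4   CYP1A1  bep     0.885 0.6825         strong         small
#> 5   CYP1B1   uM     0.959 0.1239         strong         small
#> 6   CYP1B1  bep     0.933 0.5937         strong         small
#> 7     GSTA   uM     0.982 0.1841         strong         small
#> 8     GSTA  bep     0.981 0.2928         strong         small
#> 9    HMOX1   uM     0.994 0.0883         strong         small
#> 10   HMOX1  bep     0.557 0.2848         strong         small
#> 11    NQO1   uM     0.993 0.1744         strong         small
#> 12    NQO1  bep        NA 0.3167 not-computable         small
```

Six of the nine genes pass the three-significant-components rule. On the
micromolar axis — the axis on which this synthetic dataset was generated
additively — the IA prediction tracks the mixture closely (r ≥ 0.93, RMSE
below 0.2 log2 units). The TEF-scaled axis is a genuinely different model
of the same data: agreement degrades, and for one gene the TEF-scaled
prediction is flat over the tested range so no correlation can be computed
— the same qualitative behaviors seen with real mixture data. Generating
instead with `interaction = list(mode = "synergy", s = 1.5)` makes the
additive prediction underestimate the observed response and the RMSE grow
with `s`.

## Documentation

See the vignette (`vignettes/additivity-modeling.Rmd`) for the model, its
assumptions, the tunable parameters, what the synthetic generator does and
does not emulate, and the package's numerical design choices.
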