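---
title: "Component-based additivity modeling of PAH mixture responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Component-based additivity modeling of PAH mixture responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahmix)
```

## The problem

Environmental exposure to polycyclic aromatic hydrocarbons (PAHs) is almost
always exposure to a mixture. A component-based additivity assessment asks:
if we know how each chemical in a defined mixture perturbs an endpoint on its
own, does the mixture behave as the additive combination of its parts? When
the observed mixture response exceeds the additive prediction, that is
evidence for synergistic interactions; when it falls short, for antagonism.

`pahmix` implements this workflow for transcriptional endpoints measured by
qPCR: per-gene log2 fold changes (log2FC) versus a vehicle control, for a
mixture and each of its components, assayed over a shared ladder of relative
concentrations (fractions of the full-strength mixture, e.g. 0.5%, 1%, 5%,
10%). The bundled `ToxMix` definition is a seven-PAH mixture at
environmentally derived proportions dominated by retene (68.6%), with toxic
equivalency factors (TEFs) on the benzo[e]pyrene (BeP) scale spanning three
orders of magnitude.

## The model

The additivity model is independent action (IA, also called response
addition), which does not assume a common mechanism of action across
components. For a gene, each component $i$ contributes its modeled effect
$E_i(c_i)$, the fitted dose-response curve evaluated at the component's dose
within the mixture. Because a gene's components may be split between up- and
down-regulation, effects are partitioned by direction and combined
separately; with $u_i = E_i / E^{max}_{up}$ clamped to $[0, 1]$ (analogously
$v_i$ for the down set):

$$
\widehat{\mathrm{log_2FC}}_{mix}(c) =
\Big(1 - \prod_{i \in up} (1 - u_i)\Big) E^{max}_{up} +
\Big(1 - \prod_{j \in down} (1 - v_j)\Big) E^{max}_{down}
$$

$E^{max}_{up} \ge 0$ and $E^{max}_{down} \le 0$ are the per-gene,
per-direction extrema of the fitted component effects over the modeled dose
range. The complemented product form is the standard response-addition
combination: it reduces exactly to the component's own curve when only one
component is active, is bounded between the directional maxima, and is
monotone in each normalized effect. A formulation that multiplies the
normalized effects directly (without the inner complement) circulates in
some write-ups; it violates the single-component identity and is available
in `ia_predict(..., literal = TRUE)` only for comparison.

Two concentration axes are supported:

* **uM axis** — the mixture coordinate is the total micromolar
  concentration $c$; component $i$ is evaluated at
  $c_i = p_i \cdot c$ where $p_i$ is its proportion.
* **BeP-equivalent axis** — component concentrations are scaled by their
  TEFs onto the reference-chemical scale. A component curve fit on its own
  uM axis is re-indexed so that at the common BeP-equivalent coordinate $x$
  it is evaluated at $x / \mathrm{TEF}_i$. This keeps each component's own
  response (unlike classic TEF approaches that substitute scaled
  reference-chemical responses) while weighting the axis by toxicity. A
  consequence the package's tests reproduce: components with very small
  TEFs are pushed far up their own curves, where they plateau, so the
  TEF-scaled prediction tends to follow the shape of the highest-TEF
  component.

## The pipeline

`run_pipeline()` chains the stages; each is exported on its own.

1. **Fold change.** Raw Ct input is converted by the comparative
   $\Delta\Delta C_t$ method: $\Delta C_t = C_t^{target} - C_t^{ref}$ per
   well, $\Delta\Delta C_t$ subtracts the vehicle-mean $\Delta C_t$ of the
   same gene x treatment batch, and $\mathrm{log_2FC} = -\Delta\Delta C_t$.
2. **Outlier screen.** Within each gene x treatment x concentration cell,
   optionally by Tukey IQR fences or an iterated Grubbs test. The default is
   `"none"`: the screening procedure is a reporting-sensitive choice, so it
   is opt-in and every removal is logged.
3. **Significance.** One-way ANOVA with Dunnett's many-to-one comparison of
   each concentration against vehicle, per gene x treatment; the family for
   the adjustment is the dose groups of that batch, matching per-panel
   testing, and the cutoff is an adjusted p below 0.05. Cells with zero
   residual variance (exact ties, or noise-free synthetic data) are handled
   deterministically: zero contrasts get p 1, nonzero contrasts p 0.
4. **Inclusion filters.** A treatment cell needs at least `min_obs = 2`
   valid replicate observations to stay in; a gene needs at least
   `min_components = 3` components with a significant response at any
   concentration (the mixture itself is not required to respond). The
   wording of the published observation rule is ambiguous between "two
   significant observations" and "two valid observations"; the package
   implements the valid-replicate reading, which is the one consistent with
   the worked removal example accompanying the rule, and logs every
   exclusion either way.
5. **Curve fitting.** Candidate families: log-logistic (2-4 parameter),
   Weibull type 1 and 2, Michaelis-Menten, asymptotic regression, Gompertz,
   plus linear and quadratic regression. All are parameterized with the
   conventional `b` (slope), `c` (lower asymptote), `d` (upper asymptote),
   `e` (location) names, fit by Levenberg-Marquardt least squares with a
   deterministic initialization (asymptotes from the response extremes,
   location from the dose bracketing the half response) and a fixed 5-point
   multistart on the slope or location parameter. Dose 0 (vehicle) anchors
   every fit through the families' well-defined dose-to-zero limits; no
   pseudo-dose offset is introduced.
6. **Model selection.** Gaussian AIC, $n \ln(RSS/n) + 2k$ with $k$ counting
   the curve parameters plus one for the residual variance (constants drop
   out of AIC differences; including the variance parameter uniformly keeps
   families comparable). The minimum-AIC model wins unless it is a
   polynomial, which must undercut the best saturating family by more than
   2 AIC units - polynomials describe trend but admit no EC50, so they are
   only accepted on clear evidence.
7. **EC50.** The relative EC50 is the dose at the midpoint of the modeled
   span, $c + (d - c)/2$. Every saturating family has a closed form
   (verified against grid-search oracles in the tests); polynomial or flat
   fits return no EC50 rather than an error.
8. **Evaluation.** The IA prediction is compared with the mixture response
   two ways: Pearson correlation between the fitted mixture curve and the
   IA curve over a 100-point log-spaced grid spanning the tested mixture
   dose range (curve-shape agreement; unavailable when either curve has no
   variance, e.g. a non-dose-responsive mixture), and RMSE between the IA
   prediction and the per-dose mean observed mixture log2FC (level
   agreement). Qualitative bands follow the conventional thresholds: weak
   / moderate / strong correlation at 0.3 and 0.5 on $|r|$, small /
   moderate / large error at 1 and 2 log2FC units of RMSE. The published
   inequalities are strict on both sides and leave the boundary values
   unassigned; the package assigns boundaries upward, i.e. each threshold
   is a closed lower bound of the higher category.

## The synthetic-data generator

The package ships a generator rather than data: it draws replicate-level
log2FC tables (or raw Ct tables) from known ground-truth curves, so every
pipeline stage can be verified against a known answer.

* **Design defaults** mirror the study conditions the package is built
  around: the seven-component ToxMix, relative concentrations 0.005, 0.01,
  0.05, 0.10 (below transcript-response saturation), 4 replicates (5 is
  equally supported, reflecting a genuine ambiguity in the reported design),
  and additive Gaussian noise with SD 0.3 log2 units, constant across doses
  — the natural error model for $\Delta\Delta C_t$ data, where noise is
  approximately additive in Ct space.
* **Ground truth** for the canonical scenario (`study_truth()`) assigns
  active cells 4-parameter log-logistic curves with lower asymptote 0,
  slope -1, half-max dose at half of each component's 5%-exposure dose, and
  spans scaled per gene (0.8-4 log2 units) and per component (retene most
  potent). Which gene x component cells are active comes from the bundled
  qualitative significance pattern: the bundled table encodes the reported
  per-component significance counts for the nine biomarkers, with
  individually unreported cells completed synthetically (the file carries a
  `_synthetic` suffix for that reason). All active directions are up,
  matching the predominantly inductive biomarker picture at the modeled
  timepoint.
* **The mixture response** is generated by the same IA kernel the analyzer
  uses (`ia_predict_from_truth()`, uM axis), times an interaction factor
  `s`: 1 for additivity, above 1 for synergy, below for antagonism. Sharing
  the kernel is deliberate: the closure property (additive data in,
  additive verdict out) then tests the fitting and evaluation stages, not
  two diverging formula transcriptions.
* **Determinism.** Every generator is a pure function of (config, truth,
  seed); the caller's RNG stream is saved and restored.

What passing synthetic tests do *not* show: the generator draws independent
Gaussian noise and curve-shaped means. Real qPCR data add plate effects,
primer-efficiency deviations, heteroscedasticity at high Ct, and biological
correlation between genes; none of these are simulated, so the tests
validate the arithmetic of the pipeline, not its robustness to every
real-world artifact.

## Numerical choices and edge cases

* Proportions are accepted as printed percentages summing to ~100 within
  0.5 percentage points and renormalized to exactly 1 at load time (raw
  values preserved for reporting).
* The full-strength total concentration is a required scale parameter
  (100 uM in the bundled fixtures). Correlation and RMSE are invariant to
  it; only axis labels and EC50 units change.
* Zero-max directions in an IA context contribute zero rather than dividing
  by zero; normalized effects are clamped to $[0, 1]$ because fitted curves
  can exceed the cross-component maximum when extrapolated.
* Component effects inside the IA kernel are evaluated with a constant
  (plateau) extension above the curve's largest fitted dose. Below-range
  evaluation is controlled (the families interpolate toward their vehicle
  anchor), but above-range extrapolation is not: on the BeP-equivalent axis
  a low-TEF component is re-indexed tens of times past its tested doses,
  where a polynomial winner would grow without bound and swamp the
  directional maximum. Ground-truth curves carry no fitted range and are
  evaluated exactly.
* Exact fits are kept at finite AIC by flooring the mean squared residual
  at 1e-24; only AIC differences matter and perfect fits still dominate.
* Effect direction is the sign of the largest-magnitude modeled response
  over the observed dose range, with responses under 0.1 log2 units
  classified flat (and flat curves excluded from IA and EC50).
* Non-converged fits are flagged and excluded from model selection, never
  silently zeroed; a gene whose every component fails to fit yields an
  empty context and an identically zero prediction, with the reason logged.
* Dunnett p-values from the multivariate-t integration are quasi-random;
  the package pins the integration stream locally so results are
  reproducible to well below any decision threshold.

## Verification problem sizes

The test-suite simulations are sized to be decisive yet quick: the additive
closure and synergy signatures run the full nine-gene (respectively
three-gene) pipeline at zero noise; EC50 recovery uses 200 simulated
datasets of 4 replicates x 7 geometric doses bracketing the true EC50
(median relative error stays near 20%, comfortably within the 25% bound
asserted); Dunnett calibration uses 5,000 null simulations of 4 dose groups
plus vehicle at n = 4, where the family-wise error lands within a point of
the nominal 5%. The EC50 dose placement is the package's own choice of a
standard bracketing design; estimator accuracy degrades when the tested
range ends well short of saturation, which is worth remembering when
applying the package to designs truncated at low doses.

## A worked example

```{r example, eval = FALSE}
mix <- pah_mixture("ToxMix")        # 7 PAHs, TEFs on the BeP scale
truth <- study_truth(mix)           # canonical ground-truth curve set
cfg <- simulation_config(mix, genes = unique(significance_pattern_fixture()$gene),
                         noise_sd = 0.3, seed = 17)
pc <- pipeline_config(mix, list(mode = "simulate", truth = truth, sim = cfg))
res <- run_pipeline(pc)
res$genes        # genes passing the 3-component rule
res$evaluation   # per gene x axis: r, RMSE, categories
```

## Known limitations

* The IA model interpolates (and extrapolates below the lowest tested
  single-component dose) from fitted curves; with sparse dose ladders the
  prediction inherits the fit's extrapolation behavior, which is logged but
  not penalized.
* No confidence intervals on EC50 or on the r/RMSE comparison are provided;
  the additivity verdict is descriptive, as in the assessment framework the
  package implements.
* Concentration addition and generalized concentration addition are out of
  scope; the package deliberately implements only the IA family of
  additivity models.
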