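Package: pahmix
Title: Component-Based Additivity Modeling of PAH Mixture Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for component-based additivity assessment of chemical
    mixtures, developed around transcriptional (qPCR log2 fold-change)
    dose-response data for polycyclic aromatic hydrocarbon (PAH) mixtures.
    Provides mixture composition objects with toxic-equivalency-factor (TEF)
    concentration scaling, delta-delta-Ct fold-change computation, outlier
    screening and Dunnett many-to-one significance testing, a family of
    dose-response models with AIC-based selection and EC50 extraction, a
    modified independent-action (IA) mixture model supporting both micromolar
    and benzo[e]pyrene-equivalent concentration axes, Pearson/RMSE model
    evaluation with qualitative categories, a synthetic-data generator with
    known ground truth, and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    multcomp,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
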