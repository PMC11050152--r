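## Synthetic qPCR-style data generator with known ground truth.
##
## Emulates the study design that motivates the package: mixture components
## assayed singly at relative concentrations 0.5/1/5/10% of the full-strength
## mixture, vehicle-normalized log2 fold changes with additive Gaussian noise
## on the log2 scale, and a mixture response generated under independent
## action (optionally scaled by a synergy/antagonism factor).

#' Ground-truth curve for one gene x treatment
#'
#' @param gene,treatment Identifiers.
#' @param family Dose-response family name, or `"null"` for an inactive
#'   (identically zero) response.
#' @param params Named family parameters.
#' @param direction `"up"`, `"down"` or `"null"`; inferred from the curve
#'   when omitted (sign of the largest-magnitude response over `dose_range`).
#' @param dose_range Dose range used for direction inference.
#' @return A `dr_curve` tagged with the ground-truth direction.
#' @export
true_curve <- function(gene, treatment, family, params = numeric(0),
                       direction = NULL, dose_range = c(1e-3, 10)) {
  if (identical(family, "null") || identical(direction, "null")) {
    return(dr_curve("null", gene = gene, treatment = treatment,
                    direction = "flat"))
  }
  dr_curve(family, params, gene = gene, treatment = treatment,
           direction = direction, dose_range = dose_range)
}

#' Simulation configuration
#'
#' @param mixture A [mixture_definition()].
#' @param genes Character vector of gene identifiers.
#' @param rel_concs Strictly increasing relative concentrations (fractions of
#'   full strength). Default `c(0.005, 0.01, 0.05, 0.10)`, i.e. the 0.5%, 1%,
#'   5% and 10% exposures chosen to stay below transcript-response saturation.
#' @param n_replicates Replicates per gene x treatment x concentration
#'   (default 4; 5 is equally supported for designs powered that way).
#' @param noise_sd SD of the additive Gaussian noise on the log2FC scale
#'   (default 0.3 log2 units).
#' @param interaction `"additive"`, or `list(mode = "synergy", s = ...)` with
#'   `s >= 1`, or `list(mode = "antagonism", s = ...)` with `0 < s <= 1`.
#'   The mixture mean is the additive independent-action response times `s`.
#' @param outlier_prob,outlier_magnitude Optional contamination: each
#'   observation is independently replaced-shifted by
#'   `+/- outlier_magnitude` with probability `outlier_prob` (off by
#'   default), to exercise outlier screening.
#' @param seed Required integer seed; every generator call is a pure
#'   function of (config, truth).
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(mixture, genes,
                              rel_concs = c(0.005, 0.01, 0.05, 0.10),
                              n_replicates = 4L, noise_sd = 0.3,
                              interaction = "additive",
                              outlier_prob = 0, outlier_magnitude = 10,
                              seed) {
  stopifnot(inherits(mixture, "mixture_definition"),
            is.character(genes), length(genes) > 0L)
  if (any(diff(rel_concs) <= 0) || any(rel_concs <= 0) || any(rel_concs > 1)) {
    stop("'rel_concs' must be strictly increasing fractions in (0, 1]",
         call. = FALSE)
  }
  if (missing(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("an integer 'seed' is required (no hidden RNG state)", call. = FALSE)
  }
  if (is.character(interaction)) {
    interaction <- list(mode = match.arg(interaction,
                                         c("additive", "synergy",
                                           "antagonism")),
                        s = 1)
  }
  if (identical(interaction$mode, "synergy") && interaction$s < 1) {
    stop("synergy factor s must be >= 1", call. = FALSE)
  }
  if (identical(interaction$mode, "antagonism") &&
      (interaction$s <= 0 || interaction$s > 1)) {
    stop("antagonism factor s must be in (0, 1]", call. = FALSE)
  }
  if (identical(interaction$mode, "additive")) interaction$s <- 1
  structure(list(mixture = mixture, genes = genes,
                 rel_concs = as.numeric(rel_concs),
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd, interaction = interaction,
                 outlier_prob = outlier_prob,
                 outlier_magnitude = outlier_magnitude,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.truth_key <- function(gene, treatment) paste(gene, treatment, sep = "\r")

#' Index a list of ground-truth curves by gene x treatment
#'
#' @param truth List of [true_curve()] objects.
#' @return Named list keyed internally by gene and treatment.
#' @export
truth_set <- function(truth) {
  if (inherits(truth, "truth_set")) return(truth)
  stopifnot(is.list(truth))
  keys <- vapply(truth, function(tc) .truth_key(tc$gene, tc$treatment),
                 character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate gene x treatment entries in truth set", call. = FALSE)
  }
  structure(stats::setNames(truth, keys), class = "truth_set")
}

.truth_lookup <- function(truth, gene, treatment) {
  tc <- truth[[.truth_key(gene, treatment)]]
  if (is.null(tc)) {
    stop(sprintf("no ground-truth curve for gene '%s', treatment '%s'",
                 gene, treatment), call. = FALSE)
  }
  tc
}

.truth_component_curves <- function(truth, gene, mix) {
  curves <- lapply(mix$components$component, function(cm) {
    tc <- .truth_lookup(truth, gene, cm)
    if (identical(tc$family, "null")) NULL else tc
  })
  stats::setNames(curves, mix$components$component)
}

.sim_inject_outliers <- function(x, config) {
  if (config$outlier_prob <= 0) return(x)
  hit <- stats::runif(length(x)) < config$outlier_prob
  x[hit] <- x[hit] + sample(c(-1, 1), sum(hit), replace = TRUE) *
    config$outlier_magnitude
  x
}

.response_row_block <- function(gene, treatment, rel_conc, n_rep, means,
                                noise_sd, config) {
  obs <- means + stats::rnorm(n_rep, 0, noise_sd)
  obs <- .sim_inject_outliers(obs, config)
  data.frame(gene = gene, treatment = treatment, rel_conc = rel_conc,
             replicate = seq_len(n_rep), log2fc = obs,
             stringsAsFactors = FALSE)
}

#' Generate replicate-level component responses
#'
#' For every gene x component x relative concentration (plus vehicle at 0),
#' draws `n_replicates` observations `true_mean + N(0, noise_sd)` where the
#' true mean is the component's ground-truth curve evaluated at its
#' within-mixture dose `rel_conc * full_strength_total * proportion`.
#' Vehicle rows have mean 0. Deterministic given the config seed.
#'
#' @param config A [simulation_config()].
#' @param truth A [truth_set()] (or plain list of [true_curve()]s) covering
#'   every gene x component pair.
#' @return A long-format response data frame with columns `gene`,
#'   `treatment`, `rel_conc`, `replicate`, `log2fc`.
#' @export
generate_component_responses <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- truth_set(truth)
  mix <- config$mixture
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  blocks <- list()
  for (g in config$genes) {
    for (cm in mix$components$component) {
      tc <- .truth_lookup(truth, g, cm)
      blocks[[length(blocks) + 1L]] <- .response_row_block(
        g, cm, 0, config$n_replicates, 0, config$noise_sd, config)
      for (r in config$rel_concs) {
        mu <- evaluate_curve(tc, component_dose(mix, r, cm))
        blocks[[length(blocks) + 1L]] <- .response_row_block(
          g, cm, r, config$n_replicates, mu, config$noise_sd, config)
      }
    }
  }
  do.call(rbind, blocks)
}

#' Generate replicate-level mixture responses
#'
#' The mixture mean at relative concentration `r` is the independent-action
#' combination of the ground-truth component curves (micromolar axis,
#' [ia_predict_from_truth()]) at total mixture dose
#' `r * full_strength_total`, multiplied by the interaction factor `s`
#' (`s = 1` under additivity). Noise as in
#' [generate_component_responses()].
#'
#' @inheritParams generate_component_responses
#' @return Long-format response data frame; `treatment` is the mixture name.
#' @export
generate_mixture_response <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- truth_set(truth)
  mix <- config$mixture
  s <- config$interaction$s
  doses <- config$rel_concs * mix$full_strength_total
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  blocks <- list()
  for (g in config$genes) {
    curves <- .truth_component_curves(truth, g, mix)
    mu <- ia_predict_from_truth(curves, mix, doses, axis = "uM",
                                dose_range = range(doses))$grid$predicted * s
    blocks[[length(blocks) + 1L]] <- .response_row_block(
      g, mix$name, 0, config$n_replicates, 0, config$noise_sd, config)
    for (i in seq_along(config$rel_concs)) {
      blocks[[length(blocks) + 1L]] <- .response_row_block(
        g, mix$name, config$rel_concs[i], config$n_replicates, mu[i],
        config$noise_sd, config)
    }
  }
  do.call(rbind, blocks)
}

#' True (noise-free) mixture means for a config
#'
#' Convenience accessor used in tests and closure checks: the generating
#' mixture mean at each configured relative concentration, per gene.
#'
#' @inheritParams generate_component_responses
#' @return Data frame with columns `gene`, `rel_conc`, `dose_uM`, `mean`.
#' @export
true_mixture_means <- function(config, truth) {
  truth <- truth_set(truth)
  mix <- config$mixture
  doses <- config$rel_concs * mix$full_strength_total
  out <- lapply(config$genes, function(g) {
    curves <- .truth_component_curves(truth, g, mix)
    mu <- ia_predict_from_truth(curves, mix, doses, axis = "uM",
                                dose_range = range(doses))$grid$predicted
    data.frame(gene = g, rel_conc = config$rel_concs, dose_uM = doses,
               mean = mu * config$interaction$s, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate a raw Ct table
#'
#' Emits target and reference-gene Ct values whose delta-delta-Ct fold
#' changes ([fold_change_from_ct()]) reproduce the intended component
#' log2 fold changes exactly at `noise_sd = 0` (noise, when present, is
#' applied in Ct space, where the delta-delta-Ct error model is additive).
#'
#' @inheritParams generate_component_responses
#' @param reference_gene Name of the normalizer gene (default `"PPIA"`).
#' @param base_ct_reference,base_delta_ct Baseline reference Ct and baseline
#'   target-minus-reference Ct difference for vehicle wells.
#' @return Data frame with columns `gene`, `treatment`, `rel_conc`,
#'   `replicate`, `ct_target`, `ct_reference`, `reference_gene`.
#' @export
generate_ct_table <- function(config, truth, reference_gene = "PPIA",
                              base_ct_reference = 20, base_delta_ct = 5) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- truth_set(truth)
  mix <- config$mixture
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)  # same stream as generate_component_responses
  blocks <- list()
  for (g in config$genes) {
    for (cm in mix$components$component) {
      tc <- .truth_lookup(truth, g, cm)
      for (r in c(0, config$rel_concs)) {
        mu <- if (r == 0) 0 else evaluate_curve(tc, component_dose(mix, r, cm))
        l2fc <- mu + stats::rnorm(config$n_replicates, 0, config$noise_sd)
        l2fc <- .sim_inject_outliers(l2fc, config)
        blocks[[length(blocks) + 1L]] <- data.frame(
          gene = g, treatment = cm, rel_conc = r,
          replicate = seq_len(config$n_replicates),
          ct_target = base_ct_reference + base_delta_ct - l2fc,
          ct_reference = base_ct_reference,
          reference_gene = reference_gene, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, blocks)
}

## RNG bookkeeping: generators set their own seed but must not disturb the
## caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Canonical study-conditions ground truth
#'
#' A ready-made ground-truth curve set emulating the transcriptional study
#' design the generator stands in for: nine biomarker genes, seven mixture
#' components, activity pattern taken from
#' [significance_pattern_fixture()] (two genes inactive throughout, one gene
#' active for only two components, the rest active for 3-7 components).
#' Active cells get 4-parameter log-logistic curves with lower asymptote 0
#' (vehicle anchor), slope `b = -1`, half-max dose at half of each
#' component's 5%-exposure dose (so curves rise over, and saturate near the
#' top of, the tested 0.5-10% range), and maximal responses scaled by a
#' per-gene span times a per-component potency weight (the most abundant
#' component being the most bioactive). All active directions are up,
#' matching the predominantly inductive 24 h biomarker picture.
#'
#' @param mix The ToxMix [mixture_definition()] (component names must match
#'   the fixture).
#' @param genes Optional subset of the nine fixture genes.
#' @return List of [true_curve()] objects covering every gene x component.
#' @export
study_truth <- function(mix, genes = NULL) {
  pat <- significance_pattern_fixture()
  if (is.null(genes)) genes <- unique(pat$gene)
  stopifnot(all(genes %in% pat$gene),
            all(unique(pat$treatment) %in% mix$components$component))
  gene_span <- c(CYP1A1 = 4, CYP1B1 = 3, ALDH3A1 = 1.5, GSTA = 1.2,
                 HMOX1 = 1.1, NQO1 = 1.0, TJP2 = 0.8, GJA1 = 0, DDB2 = 0)
  potency <- c("Retene" = 1, "Benzo[a]fluorene" = 0.8,
               "Benzo[b]fluorene" = 0.8, "Benzo[c]fluorene" = 0.5,
               "Triphenylene" = 0.5, "Benzo[e]pyrene" = 0.4,
               "Benzo[ghi]perylene" = 0.5)
  truth <- list()
  for (g in genes) {
    for (cm in mix$components$component) {
      active <- pat$significant[pat$gene == g & pat$treatment == cm]
      p_i <- mix$components$proportion[mix$components$component == cm]
      truth[[length(truth) + 1L]] <- if (length(active) && active &&
                                         gene_span[[g]] > 0) {
        true_curve(g, cm, "log-logistic-4",
                   c(b = -1, c = 0, d = gene_span[[g]] * potency[[cm]],
                     e = 0.5 * 0.05 * mix$full_strength_total * p_i))
      } else {
        true_curve(g, cm, "null")
      }
    }
  }
  truth
}
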