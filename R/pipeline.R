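## End-to-end orchestration: (simulate | load) -> fold change -> outlier
## screen -> Dunnett significance -> inclusion filters -> component and
## mixture dose-response fits -> independent-action prediction -> r / RMSE
## evaluation. Deterministic given (config, seed); every exclusion is logged
## exactly once; a manifest records seeds, counts and settings.

#' Pipeline configuration
#'
#' @param mixture A [mixture_definition()].
#' @param input One of:
#'   `list(mode = "simulate", truth = <truth list>, sim = <simulation_config>)`,
#'   `list(mode = "log2fc", table = <response df>)`,
#'   `list(mode = "ct", table = <ct df>)`.
#' @param outlier_method,outlier_k,outlier_alpha Passed to
#'   [remove_outliers()].
#' @param min_obs Minimum valid observations per treatment cell
#'   ([filter_treatments()]).
#' @param min_components Minimum significant components per gene
#'   ([select_genes_for_ia()]).
#' @param families Candidate dose-response families.
#' @param axes Concentration axes to run: subset of `c("uM", "bep")`.
#' @param grid_size Pearson correlation grid size.
#' @param alpha Adjusted-p significance cutoff.
#' @param output_dir Optional directory for stage artifacts (CSV/JSONL/JSON).
#' @param seed Seed for any stochastic stage (required in simulate mode).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(mixture, input,
                            outlier_method = "none", outlier_k = 1.5,
                            outlier_alpha = 0.05,
                            min_obs = 2L, min_components = 3L,
                            families = .default_families,
                            axes = c("uM", "bep"), grid_size = 100L,
                            alpha = 0.05, output_dir = NULL, seed = NULL) {
  stopifnot(inherits(mixture, "mixture_definition"))
  stopifnot(is.list(input), input$mode %in% c("simulate", "log2fc", "ct"))
  axes <- match.arg(axes, c("uM", "bep"), several.ok = TRUE)
  if (input$mode == "simulate") {
    stopifnot(inherits(input$sim, "simulation_config"))
    if (is.null(seed)) seed <- input$sim$seed
  }
  if ("bep" %in% axes && anyNA(mixture$components$tef)) {
    stop("BeP-equivalent axis requested but mixture has components without ",
         "TEFs", call. = FALSE)
  }
  structure(list(mixture = mixture, input = input,
                 outlier_method = outlier_method, outlier_k = outlier_k,
                 outlier_alpha = outlier_alpha,
                 min_obs = as.integer(min_obs),
                 min_components = as.integer(min_components),
                 families = families, axes = axes,
                 grid_size = as.integer(grid_size), alpha = alpha,
                 output_dir = output_dir, seed = seed),
            class = "pipeline_config")
}

.pipeline_input_table <- function(config) {
  inp <- config$input
  switch(inp$mode,
         simulate = {
           sim <- inp$sim
           rbind(generate_component_responses(sim, inp$truth),
                 generate_mixture_response(sim, inp$truth))
         },
         log2fc = inp$table,
         ct = fold_change_from_ct(inp$table))
}

#' Run the full additivity-analysis pipeline
#'
#' Executes the stages in order and returns every intermediate artifact plus
#' a manifest. Rerunning with an identical config (same seed) reproduces the
#' result bit-identically. If `output_dir` is set, stage outputs are written
#' as CSV / JSON-lines / JSON files.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list: `responses` (post-filter table),
#'   `outlier_log`, `significance`, `treatment_log`, `genes`,
#'   `component_fits`, `mixture_fits`, `contexts`, `predictions`,
#'   `evaluation` (per gene x axis data frame), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  mix <- config$mixture
  raw <- .pipeline_input_table(config)

  ol <- remove_outliers(raw, config$outlier_method, config$outlier_k,
                        config$outlier_alpha)
  significance <- significance_table(ol$table, config$alpha)
  ft <- filter_treatments(ol$table, config$min_obs)
  genes <- select_genes_for_ia(
    significance, config$min_components,
    exclude_treatments = mix$name)
  genes <- intersect(genes, unique(ft$table$gene))

  comp_names <- mix$components$component
  fit_log <- list()
  component_fits <- list()
  mixture_fits <- list()
  contexts <- list()
  predictions <- list()
  eval_rows <- list()

  for (g in genes) {
    sig_g <- significance[significance$gene == g &
                            significance$treatment != mix$name &
                            significance$significant, ]
    sig_comps <- unique(sig_g$treatment)
    curves <- stats::setNames(vector("list", length(comp_names)), comp_names)
    for (cm in intersect(sig_comps, comp_names)) {
      d <- ft$table[ft$table$gene == g & ft$table$treatment == cm, ]
      doses <- vapply(d$rel_conc, function(r) component_dose(mix, r, cm),
                      numeric(1))
      cands <- fit_all_families(doses, d$log2fc, config$families, g, cm)
      cv <- tryCatch(select_model(cands), error = function(e) NULL)
      if (is.null(cv)) {
        fit_log[[length(fit_log) + 1L]] <- data.frame(
          gene = g, treatment = cm, reason = "no converged fit",
          stringsAsFactors = FALSE)
      } else {
        curves[[cm]] <- cv
      }
    }
    component_fits[[g]] <- curves

    md <- ft$table[ft$table$gene == g & ft$table$treatment == mix$name, ]
    for (axis in config$axes) {
      tested <- sort(unique(md$rel_conc[md$rel_conc > 0]))
      dose_range <- range(.mixture_axis_dose(mix, tested, axis))
      ctx <- build_context(g, curves, mix, axis = axis,
                           dose_range = dose_range,
                           significant = sig_comps)
      contexts[[paste(g, axis, sep = ".")]] <- ctx
      pred <- ia_predict(ctx, dose_grid(dose_range, config$grid_size))
      predictions[[paste(g, axis, sep = ".")]] <- pred
      mix_doses <- .mixture_axis_dose(mix, md$rel_conc, axis)
      mix_cv <- tryCatch(
        select_model(fit_all_families(mix_doses, md$log2fc,
                                      config$families, g, mix$name)),
        error = function(e) NULL)
      mixture_fits[[paste(g, axis, sep = ".")]] <- mix_cv
      eval_rows[[paste(g, axis, sep = ".")]] <-
        evaluate_gene(mix_cv, ctx, md, config$grid_size)
    }
  }

  evaluation <- if (length(eval_rows)) do.call(rbind, eval_rows) else
    data.frame(gene = character(0), axis = character(0),
               pearson_r = numeric(0), rmse = numeric(0),
               r_category = character(0), rmse_category = character(0))
  rownames(evaluation) <- NULL
  fit_log <- if (length(fit_log)) do.call(rbind, fit_log) else
    data.frame(gene = character(0), treatment = character(0),
               reason = character(0), stringsAsFactors = FALSE)

  manifest <- list(
    package = "pahmix",
    version = as.character(utils::packageVersion("pahmix")),
    seed = config$seed,
    mixture = mix$name,
    input_mode = config$input$mode,
    settings = list(outlier_method = config$outlier_method,
                    min_obs = config$min_obs,
                    min_components = config$min_components,
                    axes = config$axes, grid_size = config$grid_size,
                    alpha = config$alpha,
                    families = config$families),
    counts = list(input_rows = nrow(raw),
                  outliers_removed = sum(ol$log$reason %in%
                                           sprintf("outlier (%s)",
                                                   config$outlier_method)),
                  rows_after_outliers = nrow(ol$table),
                  cells_dropped = nrow(ft$log),
                  rows_after_treatment_filter = nrow(ft$table),
                  genes_evaluated = length(unique(raw$gene)),
                  genes_included = length(genes)),
    genes_included = as.character(genes),
    evaluation = evaluation)

  result <- structure(
    list(responses = ft$table, raw_responses = raw, outlier_log = ol$log,
         significance = significance, treatment_log = ft$log,
         fit_log = fit_log, genes = as.character(genes),
         component_fits = component_fits, mixture_fits = mixture_fits,
         contexts = contexts, predictions = predictions,
         evaluation = evaluation, manifest = manifest),
    class = "pipeline_result")

  if (!is.null(config$output_dir)) {
    .write_pipeline_outputs(result, config)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pahmix pipeline: %d genes included (%s)\n",
              length(x$genes), paste(x$genes, collapse = ", ")))
  print(x$evaluation, row.names = FALSE)
  invisible(x)
}

.write_pipeline_outputs <- function(result, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$output_dir, f)
  write_response_csv(result$responses, p("responses.csv"))
  sig <- result$significance
  sig$rel_conc_percent <- sig$rel_conc * 100
  utils::write.csv(sig[, c("gene", "treatment", "rel_conc_percent", "p_adj",
                           "significant")], p("significance.csv"),
                   row.names = FALSE)
  write_exclusion_log(result$outlier_log, p("exclusions_outliers.jsonl"),
                      stage = "outlier_removal")
  write_exclusion_log(result$treatment_log, p("exclusions_treatments.jsonl"),
                      stage = "treatment_filter")
  write_exclusion_log(result$fit_log, p("exclusions_fits.jsonl"),
                      stage = "curve_fitting")
  all_fits <- c(unlist(result$component_fits, recursive = FALSE),
                result$mixture_fits)
  all_fits <- Filter(Negate(is.null), all_fits)
  if (length(all_fits)) {
    utils::write.csv(curves_summary(all_fits), p("fits.csv"),
                     row.names = FALSE)
  }
  preds <- do.call(rbind, lapply(result$predictions, function(pr) {
    cbind(data.frame(gene = pr$gene, axis = pr$axis), pr$grid)
  }))
  if (!is.null(preds)) {
    utils::write.csv(preds, p("ia_predictions.csv"), row.names = FALSE)
  }
  utils::write.csv(result$evaluation, p("evaluation.csv"), row.names = FALSE)
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
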