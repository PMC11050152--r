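## Fold-change computation (delta-delta-Ct), outlier screening, Dunnett
## many-to-one significance testing against vehicle, and the inclusion
## filters applied before independent-action modeling.

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' log2 fold changes from raw Ct values (delta-delta-Ct)
#'
#' Per well, `dCt = ct_target - ct_reference`; per gene x treatment,
#' `ddCt = dCt - mean(dCt of vehicle wells)`; the reported response is
#' `log2fc = -ddCt` (fold change `2^-ddCt`). Invariant to any constant added
#' to both target and reference Ct of a well, and to reference-gene shifts
#' applied across all wells of a batch.
#'
#' @param ct Data frame with columns `gene`, `treatment`, `rel_conc`
#'   (0 = vehicle), `replicate`, `ct_target`, `ct_reference`.
#' @return Response data frame (`gene`, `treatment`, `rel_conc`,
#'   `replicate`, `log2fc`).
#' @export
fold_change_from_ct <- function(ct) {
  .require_cols(ct, c("gene", "treatment", "rel_conc", "replicate",
                      "ct_target", "ct_reference"), "Ct table")
  if (any(!is.finite(ct$ct_target)) || any(!is.finite(ct$ct_reference)) ||
      any(ct$ct_target <= 0) || any(ct$ct_reference <= 0)) {
    stop("Ct values must be finite and positive", call. = FALSE)
  }
  key <- interaction(ct$gene, ct$treatment, drop = TRUE)
  out <- lapply(split(ct, key), function(d) {
    veh <- d$rel_conc == 0
    if (!any(veh)) {
      stop(sprintf("no vehicle (rel_conc = 0) wells for gene '%s', treatment '%s'",
                   d$gene[1], d$treatment[1]), call. = FALSE)
    }
    dct <- d$ct_target - d$ct_reference
    ddct <- dct - mean(dct[veh])
    data.frame(gene = d$gene, treatment = d$treatment,
               rel_conc = d$rel_conc, replicate = d$replicate,
               log2fc = -ddct, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.grubbs_crit <- function(n, alpha) {
  # one-outlier two-sided Grubbs critical value
  t2 <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

.flag_outliers_cell <- function(x, method, k, alpha) {
  # returns logical flags for one gene x treatment x rel_conc cell
  flag <- rep(FALSE, length(x))
  if (method == "iqr") {
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    flag <- x < q[1] - k * iqr | x > q[2] + k * iqr
  } else if (method == "grubbs") {
    idx <- seq_along(x)
    repeat {
      keep <- idx[!flag[idx]]
      n <- length(keep)
      if (n < 3L) break
      s <- stats::sd(x[keep])
      if (s == 0) break
      g <- abs(x[keep] - mean(x[keep])) / s
      i <- which.max(g)
      if (g[i] > .grubbs_crit(n, alpha)) flag[keep[i]] <- TRUE else break
    }
  }
  flag
}

#' Remove outlying replicate observations
#'
#' Outliers are screened within each gene x treatment x relative-concentration
#' cell. Methods: `"none"` (default; screening is an auditable choice, not a
#' silent step), `"iqr"` (Tukey fences at `k` times the interquartile range)
#' or `"grubbs"` (iterated two-sided Grubbs test at level `alpha`). Cells
#' with fewer than 3 observations are never screened (and are logged).
#'
#' @param table Response data frame (`gene`, `treatment`, `rel_conc`,
#'   `replicate`, `log2fc`).
#' @param method `"none"`, `"iqr"` or `"grubbs"`.
#' @param k IQR fence multiplier.
#' @param alpha Grubbs significance level.
#' @return List with `table` (retained rows) and `log` (one row per dropped
#'   or skipped record: `gene`, `treatment`, `rel_conc`, `replicate`,
#'   `log2fc`, `reason`).
#' @export
remove_outliers <- function(table, method = c("none", "iqr", "grubbs"),
                            k = 1.5, alpha = 0.05) {
  method <- match.arg(method)
  .require_cols(table, c("gene", "treatment", "rel_conc", "replicate",
                         "log2fc"), "response table")
  log_rows <- list()
  if (method == "none") {
    return(list(table = table,
                log = data.frame(gene = character(0), treatment = character(0),
                                 rel_conc = numeric(0), replicate = integer(0),
                                 log2fc = numeric(0), reason = character(0),
                                 stringsAsFactors = FALSE)))
  }
  key <- interaction(table$gene, table$treatment, table$rel_conc, drop = TRUE)
  keep <- rep(TRUE, nrow(table))
  for (cell in split(seq_len(nrow(table)), key)) {
    x <- table$log2fc[cell]
    if (length(x) < 3L) {
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        table[cell[1], c("gene", "treatment", "rel_conc")],
        replicate = NA_integer_, log2fc = NA_real_,
        reason = "cell size < 3: not screened", stringsAsFactors = FALSE)
      next
    }
    flag <- .flag_outliers_cell(x, method, k, alpha)
    if (any(flag)) {
      keep[cell[flag]] <- FALSE
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        table[cell[flag], c("gene", "treatment", "rel_conc", "replicate",
                            "log2fc")],
        reason = sprintf("outlier (%s)", method), stringsAsFactors = FALSE)
    }
  }
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(gene = character(0), treatment = character(0),
               rel_conc = numeric(0), replicate = integer(0),
               log2fc = numeric(0), reason = character(0),
               stringsAsFactors = FALSE)
  rownames(log) <- NULL
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(table = out, log = log)
}

#' Dunnett many-to-one test of dose groups against vehicle
#'
#' One-way ANOVA followed by Dunnett's multiple-comparison procedure for each
#' non-vehicle concentration against the vehicle control, with family-wise
#' adjustment across the dose groups of the given gene x treatment (via
#' \pkg{multcomp}). Degenerate cells (zero residual variance) do not error:
#' exact-tie contrasts get `p_adj = 1` and nonzero contrasts with zero
#' residual variance get `p_adj = 0`, with a warning.
#'
#' @param table Response data frame.
#' @param gene,treatment Identifiers selecting one batch.
#' @param alpha Significance cutoff applied to the adjusted p-values.
#' @return Data frame with one row per non-vehicle concentration: `gene`,
#'   `treatment`, `rel_conc`, `p_adj`, `significant`.
#' @export
dunnett_vs_control <- function(table, gene, treatment, alpha = 0.05) {
  .require_cols(table, c("gene", "treatment", "rel_conc", "log2fc"),
                "response table")
  d <- table[table$gene == gene & table$treatment == treatment, ]
  if (!any(d$rel_conc == 0)) {
    stop(sprintf("no vehicle group for gene '%s', treatment '%s'",
                 gene, treatment), call. = FALSE)
  }
  sizes <- table(d$rel_conc)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    stop(sprintf("groups with < 2 observations for gene '%s', treatment '%s': rel_conc %s",
                 gene, treatment, paste(small, collapse = ", ")),
         call. = FALSE)
  }
  concs <- sort(unique(d$rel_conc[d$rel_conc > 0]))
  if (length(concs) < 2L) {
    stop("need at least two non-vehicle dose groups", call. = FALSE)
  }
  grp <- factor(d$rel_conc, levels = c(0, concs))
  gm <- tapply(d$log2fc, grp, mean)
  resid_ss <- sum((d$log2fc - gm[as.character(d$rel_conc)])^2)
  if (resid_ss < 1e-20 * max(1, sum(d$log2fc^2))) {
    warning(sprintf("zero residual variance for gene '%s', treatment '%s'; degenerate p-values assigned",
                    gene, treatment))
    diffs <- gm[as.character(concs)] - gm["0"]
    p <- ifelse(abs(diffs) < 1e-12, 1, 0)
  } else {
    dd <- data.frame(y = d$log2fc, g = grp)
    fit <- stats::aov(y ~ g, data = dd)
    # multcomp's multivariate-t integration is quasi-random; pin the stream
    # locally so p-values are reproducible
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(20240101L)
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    p <- as.numeric(summary(gl)$test$pvalues)
  }
  data.frame(gene = gene, treatment = treatment, rel_conc = concs,
             p_adj = unname(p), significant = unname(p) < alpha,
             stringsAsFactors = FALSE)
}

#' Significance table for every gene x treatment batch
#'
#' @param table Response data frame.
#' @param alpha Adjusted-p cutoff.
#' @return Row-bound [dunnett_vs_control()] results for all batches.
#' @export
significance_table <- function(table, alpha = 0.05) {
  batches <- unique(table[, c("gene", "treatment")])
  out <- mapply(function(g, tr) dunnett_vs_control(table, g, tr, alpha),
                batches$gene, batches$treatment, SIMPLIFY = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Drop under-observed treatment cells
#'
#' Enforces the inclusion rule of a minimum number of valid replicate
#' observations per gene x treatment x concentration cell (after outlier
#' removal); cells falling short are dropped and logged. Vehicle cells
#' (rel_conc 0) are subject to the same rule.
#'
#' @param table Response data frame.
#' @param min_obs Minimum retained observations per cell (default 2).
#' @return List with `table` (retained rows) and `log` (dropped cells with
#'   counts and reason).
#' @export
filter_treatments <- function(table, min_obs = 2L) {
  stopifnot(min_obs >= 1L)
  .require_cols(table, c("gene", "treatment", "rel_conc", "log2fc"),
                "response table")
  key <- interaction(table$gene, table$treatment, table$rel_conc, drop = TRUE)
  counts <- table(key)
  bad <- names(counts)[counts < min_obs]
  keep <- !(as.character(key) %in% bad)
  log <- unique(table[!keep, c("gene", "treatment", "rel_conc")])
  if (nrow(log)) {
    log$n_obs <- as.integer(counts[as.character(
      interaction(log$gene, log$treatment, log$rel_conc))])
    log$reason <- sprintf("fewer than %d valid observations", min_obs)
  } else {
    log <- data.frame(gene = character(0), treatment = character(0),
                      rel_conc = numeric(0), n_obs = integer(0),
                      reason = character(0), stringsAsFactors = FALSE)
  }
  rownames(log) <- NULL
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(table = out, log = log)
}

#' Select genes eligible for independent-action modeling
#'
#' A gene qualifies when at least `min_components` mixture components show a
#' significant response at any tested concentration. The mixture treatment
#' itself is excluded from the count (the mixture is not required to respond
#' significantly).
#'
#' @param significance Data frame from [significance_table()] (`gene`,
#'   `treatment`, `rel_conc`, `significant`).
#' @param min_components Minimum number of significant components
#'   (default 3).
#' @param exclude_treatments Treatments not counted as components (the
#'   mixture name, typically).
#' @return Character vector of qualifying genes (sorted), with the
#'   per-gene significant-component counts as the `"counts"` attribute.
#' @export
select_genes_for_ia <- function(significance, min_components = 3L,
                                exclude_treatments = character(0)) {
  .require_cols(significance, c("gene", "treatment", "significant"),
                "significance table")
  s <- significance[!(significance$treatment %in% exclude_treatments), ]
  sig_pair <- unique(s[s$significant, c("gene", "treatment")])
  counts <- table(factor(sig_pair$gene, levels = sort(unique(s$gene))))
  genes <- names(counts)[counts >= min_components]
  structure(genes, counts = counts)
}
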