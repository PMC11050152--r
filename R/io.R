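## Tabular I/O. Internally relative concentrations are fractions; at the CSV
## boundary they are written/read as percents (column `rel_conc_percent`),
## matching how exposure levels are labeled (10%, 5%, 1%, 0.5%).

#' Read a long-format response table from CSV
#'
#' Expected columns: `gene`, `treatment`, `rel_conc_percent` (0 = vehicle),
#' `replicate`, `log2fc`.
#'
#' @param path CSV path.
#' @return Response data frame with `rel_conc` as a fraction.
#' @export
read_response_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("gene", "treatment", "rel_conc_percent", "replicate",
                      "log2fc"), "response CSV")
  data.frame(gene = as.character(df$gene),
             treatment = as.character(df$treatment),
             rel_conc = df$rel_conc_percent / 100,
             replicate = as.integer(df$replicate),
             log2fc = as.numeric(df$log2fc), stringsAsFactors = FALSE)
}

#' Write a response table to CSV
#'
#' @param table Response data frame (internal fraction form).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_response_csv <- function(table, path) {
  .require_cols(table, c("gene", "treatment", "rel_conc", "replicate",
                         "log2fc"), "response table")
  out <- data.frame(gene = table$gene, treatment = table$treatment,
                    rel_conc_percent = table$rel_conc * 100,
                    replicate = table$replicate, log2fc = table$log2fc)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a raw Ct table from CSV
#'
#' Expected columns: `gene`, `treatment`, `rel_conc_percent`, `replicate`,
#' `ct_target`, `ct_reference`.
#'
#' @param path CSV path.
#' @return Ct data frame with `rel_conc` as a fraction.
#' @export
read_ct_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("gene", "treatment", "rel_conc_percent", "replicate",
                      "ct_target", "ct_reference"), "Ct CSV")
  data.frame(gene = as.character(df$gene),
             treatment = as.character(df$treatment),
             rel_conc = df$rel_conc_percent / 100,
             replicate = as.integer(df$replicate),
             ct_target = as.numeric(df$ct_target),
             ct_reference = as.numeric(df$ct_reference),
             stringsAsFactors = FALSE)
}

#' Write an exclusion log as JSON lines
#'
#' One JSON object per excluded record, machine-readable for audit.
#'
#' @param log Data frame of exclusions.
#' @param path Output path (`.jsonl`).
#' @param stage Stage label added to every record.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(log, path, stage = NA_character_) {
  con <- file(path, open = "w")
  on.exit(close(con))
  if (nrow(log)) {
    log$stage <- stage
    for (i in seq_len(nrow(log))) {
      writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE,
                                  na = "null", digits = NA), con)
    }
  }
  invisible(path)
}

#' Flatten fitted curves to a summary data frame
#'
#' @param curves List of `dr_curve` objects.
#' @return Data frame with one row per curve: identifiers, family, rss, aic,
#'   ec50, direction and convergence flag.
#' @export
curves_summary <- function(curves) {
  rows <- lapply(curves, function(cv) {
    data.frame(gene = cv$gene, treatment = cv$treatment, family = cv$family,
               rss = if (is.null(cv$rss)) NA_real_ else cv$rss,
               n_obs = if (is.null(cv$n_obs)) NA_integer_ else cv$n_obs,
               aic = if (is.null(cv$aic)) NA_real_ else cv$aic,
               ec50 = if (is.null(cv$ec50)) NA_real_ else cv$ec50,
               direction = cv$direction, converged = isTRUE(cv$converged),
               params = paste(sprintf("%s=%.8g", names(cv$params),
                                      cv$params), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
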