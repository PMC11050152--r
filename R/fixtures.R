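#' Qualitative component-significance pattern for the ToxMix study design
#'
#' A gene x component table of whether each single-component exposure
#' produced a significant response at any tested concentration, for the nine
#' transcriptional biomarkers and seven ToxMix PAHs. The pattern encodes the
#' reported qualitative findings (the most active components significant for
#' six of seven responsive transcripts, the tight-junction marker TJP2
#' significant for exactly two components, two genes unresponsive
#' throughout, the most sensitive gene significant for every treatment);
#' component x gene cells that are not individually reported are synthetic
#' completions consistent with the stated per-component counts (hence the
#' `_synthetic` suffix on the bundled file).
#'
#' Feeding this table to [select_genes_for_ia()] with the default
#' three-component rule reproduces the published inclusion set of six of the
#' nine genes.
#'
#' @return Data frame with columns `gene`, `treatment`, `significant`.
#' @export
significance_pattern_fixture <- function() {
  f <- system.file("extdata", "toxmix_significance_pattern_synthetic.csv",
                   package = "pahmix", mustWork = TRUE)
  df <- utils::read.csv(f, stringsAsFactors = FALSE)
  df$significant <- as.logical(df$significant)
  df
}
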