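## Comparison of the independent-action prediction with the observed/fitted
## mixture response: Pearson correlation of the two curves over a log-spaced
## dose grid, RMSE against the per-dose observed means, and the qualitative
## agreement categories.

#' Log-spaced dose grid over a range
#'
#' @param dose_range Length-2 positive range.
#' @param n Number of points (default 100).
#' @return Numeric vector of log-equispaced doses.
#' @export
dose_grid <- function(dose_range, n = 100L) {
  stopifnot(length(dose_range) == 2L, all(dose_range > 0), n >= 2L)
  exp(seq(log(min(dose_range)), log(max(dose_range)), length.out = n))
}

#' Pearson correlation between a mixture fit and the IA prediction
#'
#' Both curves are evaluated on a common log-spaced grid spanning the tested
#' mixture dose range and the standard Pearson correlation of the paired
#' values is returned. If either curve has (numerically) zero variance over
#' the grid the correlation is undefined and `NA` is returned with a
#' `"reason"` attribute, mirroring the case of a mixture without a
#' dose-responsive fit.
#'
#' @param mix_curve Fitted `dr_curve` for the observed mixture response, on
#'   the same concentration axis as the prediction.
#' @param ia An `ia_context` (the grid is built from its dose range) or an
#'   `ia_prediction` evaluated on the desired grid.
#' @param grid_size Number of grid points when `ia` is a context.
#' @return Pearson r in `[-1, 1]`, or `NA` with attribute `reason`.
#' @export
pearson_between_curves <- function(mix_curve, ia, grid_size = 100L) {
  stopifnot(inherits(mix_curve, "dr_curve"))
  if (inherits(ia, "ia_context")) {
    ia <- ia_predict(ia, dose_grid(ia$dose_range, grid_size))
  }
  stopifnot(inherits(ia, "ia_prediction"))
  doses <- ia$grid$dose
  m <- evaluate_curve(mix_curve, doses)
  p <- ia$grid$predicted
  tol <- 1e-10 * max(1, max(abs(m)), max(abs(p)))
  if (stats::sd(m) <= tol || stats::sd(p) <= tol) {
    return(structure(NA_real_,
                     reason = "zero variance in a curve over the dose grid"))
  }
  stats::cor(m, p)
}

#' RMSE between observed mixture means and the IA prediction
#'
#' Root-mean-square error between the per-dose mean observed mixture log2FC
#' and the IA prediction at the tested (non-vehicle) doses. Set
#' `per_replicate = TRUE` to compute the RMSE over individual replicate
#' observations instead of per-dose means.
#'
#' @param observed Response data frame restricted to the mixture treatment,
#'   with `rel_conc` and `log2fc` columns.
#' @param ctx An `ia_context` on the desired axis.
#' @param per_replicate Use replicate-level residuals instead of dose means.
#' @return Nonnegative RMSE in log2FC units.
#' @export
rmse_observed_vs_model <- function(observed, ctx, per_replicate = FALSE) {
  stopifnot(inherits(ctx, "ia_context"))
  .require_cols(observed, c("rel_conc", "log2fc"), "observed mixture table")
  obs <- observed[observed$rel_conc > 0, ]
  if (nrow(obs) == 0L) stop("no non-vehicle mixture observations",
                            call. = FALSE)
  concs <- sort(unique(obs$rel_conc))
  doses <- .mixture_axis_dose(ctx$mix, concs, ctx$axis)
  pred <- ia_predict(ctx, doses)$grid$predicted
  if (per_replicate) {
    pred_by_conc <- stats::setNames(pred, as.character(concs))
    resid <- obs$log2fc - pred_by_conc[as.character(obs$rel_conc)]
  } else {
    means <- tapply(obs$log2fc, factor(obs$rel_conc, levels = concs), mean)
    resid <- as.numeric(means) - pred
  }
  sqrt(mean(resid^2))
}

#' Mixture-axis dose for a relative concentration
#'
#' @keywords internal
.mixture_axis_dose <- function(mix, rel_conc, axis) {
  if (axis == "uM") {
    rel_conc * mix$full_strength_total
  } else {
    bep_equivalent(mix, rel_conc)
  }
}

#' Qualitative agreement categories for r and RMSE
#'
#' Correlation bands: weak `|r| < 0.3`, moderate `0.3 <= |r| < 0.5`, strong
#' `|r| >= 0.5`; an unavailable correlation maps to `"not-computable"`.
#' Error bands (log2FC units): small `RMSE < 1`, moderate `1 <= RMSE < 2`,
#' large `RMSE >= 2`. Boundary values, unassigned by the strict published
#' inequalities, are assigned to the higher category.
#'
#' @param r Pearson correlation (may be `NA`).
#' @param rmse Nonnegative RMSE.
#' @return List with `r_category` and `rmse_category`.
#' @export
categorize <- function(r, rmse) {
  r_cat <- if (is.na(r)) {
    "not-computable"
  } else if (abs(r) >= 0.5) {
    "strong"
  } else if (abs(r) >= 0.3) {
    "moderate"
  } else {
    "weak"
  }
  stopifnot(is.finite(rmse), rmse >= 0)
  rmse_cat <- if (rmse >= 2) "large" else if (rmse >= 1) "moderate"
              else "small"
  list(r_category = r_cat, rmse_category = rmse_cat)
}

#' Evaluate IA model performance for one gene and axis
#'
#' @param mix_curve Fitted mixture `dr_curve` on the context's axis, or
#'   `NULL` when the mixture data did not support a dose-response fit (the
#'   correlation is then `NA`/not-computable).
#' @param ctx The gene's `ia_context`.
#' @param observed Mixture-treatment response rows for the gene.
#' @param grid_size Pearson grid size.
#' @return Data frame row: `gene`, `axis`, `pearson_r`, `rmse`,
#'   `r_category`, `rmse_category`.
#' @export
evaluate_gene <- function(mix_curve, ctx, observed, grid_size = 100L) {
  r <- if (is.null(mix_curve)) {
    structure(NA_real_, reason = "mixture lacks a dose-response fit")
  } else {
    pearson_between_curves(mix_curve, ctx, grid_size)
  }
  rmse <- rmse_observed_vs_model(observed, ctx)
  cats <- categorize(as.numeric(r), rmse)
  data.frame(gene = ctx$gene, axis = ctx$axis, pearson_r = as.numeric(r),
             rmse = rmse, r_category = cats$r_category,
             rmse_category = cats$rmse_category, stringsAsFactors = FALSE)
}
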