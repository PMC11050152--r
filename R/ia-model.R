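## Modified independent-action (IA) mixture model.
##
## Components are partitioned by direction of effect (up- / down-regulation).
## Within each direction, component effects are normalized by the directional
## maximum, combined by response addition, and rescaled:
##   up_term   = (1 - prod_i (1 - E_i / max_up))   * max_up
##   down_term = (1 - prod_i (1 - E_i / max_down)) * max_down
##   predicted = up_term + down_term
## Normalized effects are clamped to [0, 1], so up_term is bounded by
## [0, max_up] and down_term by [max_down, 0].

#' Mixture-axis dose of one component
#'
#' On the micromolar axis the mixture coordinate is the total mixture
#' concentration and component i sits at `proportion_i * c_mix`. On the
#' BeP-equivalent axis the mixture coordinate is a common TEF-scaled
#' concentration and component i's curve (fit on its own uM axis) is
#' re-indexed, i.e. evaluated at `x / tef_i`.
#'
#' @param mix A [mixture_definition()].
#' @param component Component name.
#' @param mixture_doses Doses on the mixture axis.
#' @param axis `"uM"` or `"bep"`.
#' @return Component-level uM doses at which to evaluate the component curve.
#' @keywords internal
.component_axis_dose <- function(mix, component, mixture_doses,
                                 axis = c("uM", "bep")) {
  axis <- match.arg(axis)
  row <- .mix_component_row(mix, component)
  if (axis == "uM") {
    row$proportion * mixture_doses
  } else {
    if (is.na(row$tef)) {
      stop("component '", component, "' has no TEF; BeP-equivalent axis ",
           "unavailable", call. = FALSE)
    }
    mixture_doses / row$tef
  }
}

## Fitted curves are empirical: below the fitted dose range the families'
## dose-to-zero limits give controlled interpolation toward the vehicle
## anchor, but above it extrapolation is unreliable (a polynomial winner
## grows without bound). Component effects are therefore evaluated with a
## constant (plateau) extension beyond the curve's largest fitted dose.
## Ground-truth curves carry no fitted range and are evaluated as-is.
.eval_component_effect <- function(curve, doses) {
  if (!is.null(curve$dose_max)) doses <- pmin(doses, curve$dose_max)
  evaluate_curve(curve, doses)
}

#' Build an independent-action context for one gene
#'
#' Collects the per-component fitted (or ground-truth) curves, partitions the
#' components by direction of effect, and computes the per-direction maximal
#' fitted effects over the modeled mixture dose range. Components that are
#' not significant (or have no curve) are assigned null curves and contribute
#' zero effect; flat-direction curves are excluded from both partitions.
#'
#' @param gene Gene identifier.
#' @param component_curves Named list (by component name) of `dr_curve`
#'   objects or `NULL` entries.
#' @param mix A [mixture_definition()].
#' @param axis `"uM"` (total mixture micromolar concentration) or `"bep"`
#'   (common BeP-equivalent concentration).
#' @param dose_range Length-2 range of mixture-axis doses to model over.
#' @param significant Character vector of component names with a significant
#'   response; defaults to every component that has a curve.
#' @param n_grid Grid size used to scan for the per-direction maxima.
#' @return An `ia_context` object with elements `components` (curve, mapped
#'   direction), `up`, `down`, `max_up`, `max_down`, `dose_range`, `axis`.
#' @export
build_context <- function(gene, component_curves, mix,
                          axis = c("uM", "bep"), dose_range,
                          significant = NULL, n_grid = 201L) {
  axis <- match.arg(axis)
  stopifnot(inherits(mix, "mixture_definition"),
            length(dose_range) == 2L, all(dose_range > 0))
  comp_names <- mix$components$component
  unknown <- setdiff(names(component_curves), comp_names)
  if (length(unknown)) {
    stop("curves supplied for unknown components: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(significant)) {
    significant <- names(component_curves)[
      !vapply(component_curves, is.null, logical(1))]
  }
  grid <- exp(seq(log(min(dose_range)), log(max(dose_range)),
                  length.out = n_grid))
  comps <- lapply(comp_names, function(nm) {
    curve <- component_curves[[nm]]
    if (is.null(curve) || !(nm %in% significant) ||
        !isTRUE(curve$converged)) {
      return(list(name = nm, curve = NULL, direction = "null",
                  effects = rep(0, n_grid)))
    }
    eff <- .eval_component_effect(curve,
                                  .component_axis_dose(mix, nm, grid, axis))
    dir <- curve$direction
    if (is.null(dir) || is.na(dir)) {
      m <- eff[which.max(abs(eff))]
      dir <- if (abs(m) < 0.1) "flat" else if (m > 0) "up" else "down"
    }
    list(name = nm, curve = curve, direction = dir, effects = eff)
  })
  names(comps) <- comp_names
  up <- comp_names[vapply(comps, function(x) identical(x$direction, "up"),
                          logical(1))]
  down <- comp_names[vapply(comps, function(x) identical(x$direction, "down"),
                            logical(1))]
  max_up <- if (length(up)) {
    max(0, vapply(comps[up], function(x) max(x$effects), numeric(1)))
  } else 0
  max_down <- if (length(down)) {
    min(0, vapply(comps[down], function(x) min(x$effects), numeric(1)))
  } else 0
  structure(list(gene = gene, axis = axis, mix = mix,
                 components = comps, up = up, down = down,
                 max_up = max_up, max_down = max_down,
                 dose_range = sort(as.numeric(dose_range)),
                 empty = (length(up) + length(down)) == 0L),
            class = "ia_context")
}

#' @export
print.ia_context <- function(x, ...) {
  cat(sprintf(
    "ia_context %s [%s axis]: %d up (%s), %d down (%s), max_up=%.3g, max_down=%.3g\n",
    x$gene, x$axis, length(x$up), paste(x$up, collapse = ","),
    length(x$down), paste(x$down, collapse = ","), x$max_up, x$max_down))
  invisible(x)
}

.ia_direction_term <- function(effects_mat, max_dir, literal, up = TRUE) {
  # effects_mat: doses x components of that direction
  if (ncol(effects_mat) == 0L) return(rep(0, nrow(effects_mat)))
  if (max_dir == 0) return(rep(0, nrow(effects_mat)))  # zero-max guard
  u <- effects_mat / max_dir  # positive for both directions by construction
  u <- pmin(pmax(u, 0), 1)
  combined <- if (literal) {
    # literal typeset form: 1 - prod(u_i); violates the single-component
    # identity, retained for comparison only
    1 - apply(u, 1L, prod)
  } else {
    1 - apply(1 - u, 1L, prod)
  }
  combined * max_dir
}

#' Predict the mixture response under independent action
#'
#' Evaluates the direction-partitioned response-addition model at each
#' mixture-axis dose. With a single active component the prediction reduces
#' exactly to that component's curve.
#'
#' @param ctx An `ia_context` from [build_context()].
#' @param mixture_doses Nonnegative doses on `ctx$axis`.
#' @param literal Use the literal (uncomplemented) product form instead of
#'   the standard response-addition form. For comparison only; see the
#'   package vignette.
#' @return An `ia_prediction` object: data frame `grid` with columns `dose`,
#'   `up_term`, `down_term`, `predicted`, plus `gene` and `axis` attributes.
#' @export
ia_predict <- function(ctx, mixture_doses, literal = FALSE) {
  stopifnot(inherits(ctx, "ia_context"))
  if (any(!is.finite(mixture_doses)) || any(mixture_doses < 0)) {
    stop("mixture doses must be finite and nonnegative", call. = FALSE)
  }
  nd <- length(mixture_doses)
  eff <- function(set) {
    m <- vapply(set, function(nm) {
      .eval_component_effect(
        ctx$components[[nm]]$curve,
        .component_axis_dose(ctx$mix, nm, mixture_doses, ctx$axis))
    }, numeric(nd))
    matrix(m, nrow = nd, ncol = length(set))
  }
  up_term <- .ia_direction_term(eff(ctx$up), ctx$max_up, literal)
  down_term <- .ia_direction_term(eff(ctx$down), ctx$max_down, literal)
  structure(list(gene = ctx$gene, axis = ctx$axis,
                 grid = data.frame(dose = mixture_doses,
                                   up_term = up_term,
                                   down_term = down_term,
                                   predicted = up_term + down_term)),
            class = "ia_prediction")
}

#' @export
print.ia_prediction <- function(x, ...) {
  cat(sprintf("ia_prediction %s [%s axis], %d doses, range %.3g..%.3g log2FC\n",
              x$gene, x$axis, nrow(x$grid), min(x$grid$predicted),
              max(x$grid$predicted)))
  invisible(x)
}

#' Independent-action prediction from ground-truth curves
#'
#' Same arithmetic as [ia_predict()], consuming the generator's ground-truth
#' curve set, so the synthetic-data generator and the analysis share one
#' kernel and cannot drift apart.
#'
#' @param truth_curves Named list (by component) of `dr_curve` objects or
#'   `NULL` for inactive components.
#' @param mix A [mixture_definition()].
#' @param mixture_doses Doses on the mixture axis.
#' @param axis `"uM"` or `"bep"`.
#' @param dose_range Modeling range for the directional maxima; defaults to
#'   the positive range of `mixture_doses`.
#' @return An `ia_prediction`.
#' @export
ia_predict_from_truth <- function(truth_curves, mix, mixture_doses,
                                  axis = c("uM", "bep"), dose_range = NULL) {
  axis <- match.arg(axis)
  if (is.null(dose_range)) {
    pos <- mixture_doses[mixture_doses > 0]
    if (length(pos) == 0L) pos <- mix$full_strength_total
    dose_range <- range(pos)
    if (dose_range[1] == dose_range[2]) {
      dose_range <- dose_range * c(0.5, 1)
    }
  }
  ctx <- build_context(gene = NA_character_,
                       component_curves = truth_curves, mix = mix,
                       axis = axis, dose_range = dose_range)
  ia_predict(ctx, mixture_doses)
}
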