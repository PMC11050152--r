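#' Define a mixture component
#'
#' A component of a defined chemical mixture: its name, its share of the
#' mixture, and (optionally) its toxic equivalency factor (TEF) relative to
#' the reference chemical (benzo\[e\]pyrene for the bundled PAH mixtures).
#'
#' @param name Component identifier (e.g. `"Retene"`).
#' @param proportion Unitless fraction of the mixture in `(0, 1]`.
#' @param tef Toxic equivalency factor, strictly positive, or `NA` when no
#'   TEF has been assigned to the component.
#' @return A `component_spec` object (a named list).
#' @export
component_spec <- function(name, proportion, tef = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(proportion) || length(proportion) != 1L ||
      !is.finite(proportion) || proportion <= 0 || proportion > 1) {
    stop("'proportion' must be a single number in (0, 1], got: ",
         format(proportion), call. = FALSE)
  }
  tef <- as.numeric(tef)
  if (!is.na(tef) && (!is.finite(tef) || tef <= 0)) {
    stop("'tef' must be strictly positive (or NA when unassigned), got: ",
         format(tef), call. = FALSE)
  }
  structure(list(name = name, proportion = proportion, tef = tef),
            class = "component_spec")
}

#' Define a chemical mixture
#'
#' Builds a mixture definition from component proportions (and optional TEFs).
#' Proportions are accepted as printed percentages summing to ~100 within
#' rounding; they are renormalized at construction time to sum exactly to 1,
#' with the raw values preserved in the `proportion_raw` column for reporting.
#'
#' @param name Mixture identifier (e.g. `"ToxMix"`).
#' @param components A data frame with columns `component`,
#'   `proportion_percent` and optionally `tef`, or a list of
#'   [component_spec()] objects (then proportions are fractions).
#' @param full_strength_total Total concentration, in uM, of the 100%
#'   (full-strength) mixture. Absolute stock concentrations are
#'   deployment-specific, so this is a required scale factor; all downstream
#'   correlation/RMSE results are invariant to it.
#' @param tol_percent Allowed deviation, in percentage points, of the raw
#'   proportion sum from 100%.
#' @return A `mixture_definition` object with a `components` data frame
#'   (columns `component`, `proportion` (normalized fraction),
#'   `proportion_raw` (as supplied), `tef`).
#' @examples
#' mix <- mixture_definition(
#'   "demo",
#'   data.frame(component = c("A", "B"),
#'              proportion_percent = c(75, 25),
#'              tef = c(1, 0.01)),
#'   full_strength_total = 100)
#' component_dose(mix, 0.10, "A")
#' @export
mixture_definition <- function(name, components, full_strength_total,
                               tol_percent = 0.5) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(full_strength_total) || length(full_strength_total) != 1L ||
      !is.finite(full_strength_total) || full_strength_total <= 0) {
    stop("'full_strength_total' (uM of the 100% mixture) must be > 0",
         call. = FALSE)
  }
  if (is.data.frame(components)) {
    if (!all(c("component", "proportion_percent") %in% names(components))) {
      stop("components data frame needs columns 'component' and ",
           "'proportion_percent'", call. = FALSE)
    }
    raw <- as.numeric(components$proportion_percent) / 100
    tef <- if ("tef" %in% names(components)) as.numeric(components$tef)
           else rep(NA_real_, nrow(components))
    nm <- as.character(components$component)
  } else {
    stopifnot(is.list(components), length(components) > 0L)
    components <- lapply(components, function(x) {
      if (!inherits(x, "component_spec")) {
        do.call(component_spec, as.list(x))
      } else x
    })
    nm <- vapply(components, `[[`, character(1), "name")
    raw <- vapply(components, `[[`, numeric(1), "proportion")
    tef <- vapply(components, `[[`, numeric(1), "tef")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate component names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(raw) | raw <= 0)) {
    stop("all component proportions must be finite and > 0", call. = FALSE)
  }
  bad_tef <- !is.na(tef) & (!is.finite(tef) | tef <= 0)
  if (any(bad_tef)) {
    stop("non-positive TEF for: ", paste(nm[bad_tef], collapse = ", "),
         call. = FALSE)
  }
  if (abs(sum(raw) - 1) > tol_percent / 100) {
    stop(sprintf(
      "component proportions sum to %.4f%%; must be within %.2f percentage points of 100%%",
      100 * sum(raw), tol_percent), call. = FALSE)
  }
  comp <- data.frame(component = nm,
                     proportion = raw / sum(raw),
                     proportion_raw = raw,
                     tef = tef,
                     stringsAsFactors = FALSE)
  structure(list(name = name, components = comp,
                 full_strength_total = full_strength_total),
            class = "mixture_definition")
}

#' @export
print.mixture_definition <- function(x, ...) {
  cat(sprintf("Mixture '%s': %d components, full strength %g uM\n",
              x$name, nrow(x$components), x$full_strength_total))
  print(x$components, row.names = FALSE)
  invisible(x)
}

.mix_component_row <- function(mix, component) {
  i <- match(component, mix$components$component)
  if (is.na(i)) {
    stop(sprintf("unknown component '%s' in mixture '%s' (have: %s)",
                 component, mix$name,
                 paste(mix$components$component, collapse = ", ")),
         call. = FALSE)
  }
  mix$components[i, ]
}

.check_rel_conc <- function(rel_conc) {
  if (!is.numeric(rel_conc) || any(!is.finite(rel_conc)) || any(rel_conc < 0)) {
    stop("'rel_conc' must be nonnegative finite fraction(s) of full strength",
         call. = FALSE)
  }
  rel_conc
}

#' Concentration of one component at a mixture relative concentration
#'
#' Maps a relative mixture concentration (fraction of full strength; the
#' percent notation of exposure labels like "10%" corresponds to 0.10) to the
#' micromolar concentration of a single component within the mixture:
#' `rel_conc * full_strength_total * proportion`.
#'
#' @param mix A [mixture_definition()].
#' @param rel_conc Relative concentration(s) as fraction(s) in `[0, 1]`.
#' @param component Component name.
#' @return Numeric vector of concentrations (uM), one per `rel_conc`.
#' @export
component_dose <- function(mix, rel_conc, component) {
  stopifnot(inherits(mix, "mixture_definition"))
  .check_rel_conc(rel_conc)
  row <- .mix_component_row(mix, component)
  rel_conc * mix$full_strength_total * row$proportion
}

#' Benzo[e]pyrene-equivalent concentration of the mixture
#'
#' TEF-weighted total concentration of the mixture at a relative
#' concentration: `rel_conc * full_strength_total * sum(proportion_i * tef_i)`.
#' Reported on the reference-chemical (BeP) scale.
#'
#' @inheritParams component_dose
#' @return Numeric vector of BeP-equivalent concentrations (uM).
#' @export
bep_equivalent <- function(mix, rel_conc) {
  stopifnot(inherits(mix, "mixture_definition"))
  .check_rel_conc(rel_conc)
  if (anyNA(mix$components$tef)) {
    stop(sprintf("mixture '%s' has components without TEFs (%s); cannot form BeP equivalents",
                 mix$name,
                 paste(mix$components$component[is.na(mix$components$tef)],
                       collapse = ", ")), call. = FALSE)
  }
  rel_conc * mix$full_strength_total *
    sum(mix$components$proportion * mix$components$tef)
}

#' Scale a component concentration onto the BeP-equivalent axis
#'
#' @param dose_uM Concentration(s) in uM.
#' @param tef Toxic equivalency factor (> 0).
#' @return `dose_uM * tef`, in BeP-equivalent uM.
#' @export
component_axis_transform <- function(dose_uM, tef) {
  if (!is.numeric(tef) || length(tef) != 1L || !is.finite(tef) || tef <= 0) {
    stop("'tef' must be a single strictly positive number", call. = FALSE)
  }
  stopifnot(is.numeric(dose_uM), all(dose_uM >= 0))
  dose_uM * tef
}

#' Read a mixture definition from YAML or CSV
#'
#' YAML layout: top-level `name`, `full_strength_total`, and a `components`
#' list with `component`, `proportion_percent`, and optional `tef` entries.
#' CSV layout: columns `component`, `proportion_percent`, optional `tef`;
#' name and full-strength total are then supplied as arguments.
#'
#' @param path File path (`.yaml`/`.yml` or `.csv`).
#' @param name,full_strength_total Used (and required) for CSV input;
#'   override the file values for YAML input when non-`NULL`.
#' @return A [mixture_definition()].
#' @export
read_mixture <- function(path, name = NULL, full_strength_total = NULL) {
  stopifnot(file.exists(path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    comp <- do.call(rbind, lapply(y$components, function(cc) {
      data.frame(component = cc$component,
                 proportion_percent = as.numeric(cc$proportion_percent),
                 tef = if (is.null(cc$tef)) NA_real_ else as.numeric(cc$tef),
                 stringsAsFactors = FALSE)
    }))
    mixture_definition(
      name = if (is.null(name)) y$name else name,
      components = comp,
      full_strength_total = if (is.null(full_strength_total))
        as.numeric(y$full_strength_total) else full_strength_total)
  } else {
    comp <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (is.null(name) || is.null(full_strength_total)) {
      stop("CSV mixture input requires 'name' and 'full_strength_total' arguments",
           call. = FALSE)
    }
    mixture_definition(name, comp, full_strength_total)
  }
}

#' Write a mixture definition to YAML
#'
#' Raw (as-printed) percentages are written, so a read/write round trip
#' preserves the published values bit-exactly.
#'
#' @param mix A [mixture_definition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mixture <- function(mix, path) {
  stopifnot(inherits(mix, "mixture_definition"))
  comps <- lapply(seq_len(nrow(mix$components)), function(i) {
    row <- mix$components[i, ]
    out <- list(component = row$component,
                proportion_percent = row$proportion_raw * 100)
    if (!is.na(row$tef)) out$tef <- row$tef
    out
  })
  yaml::write_yaml(list(name = mix$name,
                        full_strength_total = mix$full_strength_total,
                        components = comps), path)
  invisible(path)
}

#' Bundled PAH mixture definitions
#'
#' Loads one of the two bundled environmentally derived PAH mixtures:
#' `"ToxMix"` (seven toxicity-ranked PAHs, with TEFs on the benzo\[e\]pyrene
#' scale) or `"AbundMix"` (six abundance-ranked PAHs; no TEFs assigned).
#'
#' @param which `"ToxMix"` or `"AbundMix"`.
#' @param full_strength_total Total uM of the full-strength mixture
#'   (default 100 uM; a pure scale factor for the analysis).
#' @return A [mixture_definition()].
#' @export
pah_mixture <- function(which = c("ToxMix", "AbundMix"),
                        full_strength_total = 100) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   if (which == "ToxMix") "toxmix.yaml" else "abundmix.yaml",
                   package = "pahmix", mustWork = TRUE)
  read_mixture(f, full_strength_total = full_strength_total)
}
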