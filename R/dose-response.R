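## Dose-response model families, least-squares fitting, AIC-based model
## selection with the polynomial penalty rule, and relative EC50 extraction.
##
## Parameterizations use the conventional b/c/d/e naming: b slope, c lower
## asymptote (response as dose -> 0 for the saturating families with b < 0),
## d upper asymptote, e location (inflection / half-saturation dose).

## -- mean functions ----------------------------------------------------------
## Each is vectorized in x and defined at x = 0 through its limit, so dose 0
## (vehicle) enters the fits without a pseudo-dose offset.

.lx <- function(x) {
  # log with the x = 0 convention log(0) = -Inf and no warning
  suppressWarnings(log(x))
}

.ll4 <- function(x, b, c, d, e) {
  t <- b * (.lx(x) - log(e))
  out <- c + (d - c) / (1 + exp(t))
  out[is.nan(t)] <- (c + d) / 2  # x = 0 with b = 0
  out
}
.ll3 <- function(x, b, d, e) .ll4(x, b, 0, d, e)
.ll2 <- function(x, b, e) .ll4(x, b, 0, 1, e)
.w1 <- function(x, b, c, d, e) {
  t <- b * (.lx(x) - log(e))
  out <- c + (d - c) * exp(-exp(t))
  out[is.nan(t)] <- c + (d - c) * exp(-1)
  out
}
.w2 <- function(x, b, c, d, e) {
  t <- b * (.lx(x) - log(e))
  out <- c + (d - c) * (1 - exp(-exp(t)))
  out[is.nan(t)] <- c + (d - c) * (1 - exp(-1))
  out
}
.mm <- function(x, c, d, e) c + (d - c) * x / (e + x)
.ar <- function(x, c, d, e) c + (d - c) * (1 - exp(-x / e))
.gomp <- function(x, b, c, d, e) c + (d - c) * exp(-exp(b * (x - e)))
.lin <- function(x, b0, b1) b0 + b1 * x
.quad <- function(x, b0, b1, b2) b0 + b1 * x + b2 * x^2

## family registry: npar = number of curve parameters (k in AIC adds +1 for
## the residual variance); ec50 entries are closed forms for the relative
## EC50, the dose where the mean equals c + (d - c)/2.
.dr_families <- list(
  "log-logistic-4" = list(fun = .ll4, pars = c("b", "c", "d", "e"),
                          poly = FALSE,
                          ec50 = function(p) unname(p["e"])),
  "log-logistic-3" = list(fun = .ll3, pars = c("b", "d", "e"), poly = FALSE,
                          ec50 = function(p) unname(p["e"])),
  "log-logistic-2" = list(fun = .ll2, pars = c("b", "e"), poly = FALSE,
                          ec50 = function(p) unname(p["e"])),
  "weibull-1" = list(fun = .w1, pars = c("b", "c", "d", "e"), poly = FALSE,
                     ec50 = function(p)
                       unname(p["e"] * exp(log(log(2)) / p["b"]))),
  "weibull-2" = list(fun = .w2, pars = c("b", "c", "d", "e"), poly = FALSE,
                     ec50 = function(p)
                       unname(p["e"] * exp(log(log(2)) / p["b"]))),
  "michaelis-menten" = list(fun = .mm, pars = c("c", "d", "e"), poly = FALSE,
                            ec50 = function(p) unname(p["e"])),
  "asymptotic-regression" = list(fun = .ar, pars = c("c", "d", "e"),
                                 poly = FALSE,
                                 ec50 = function(p) unname(p["e"] * log(2))),
  "gompertz" = list(fun = .gomp, pars = c("b", "c", "d", "e"), poly = FALSE,
                    ec50 = function(p)
                      unname(p["e"] + log(log(2)) / p["b"])),
  "linear" = list(fun = .lin, pars = c("b0", "b1"), poly = TRUE, ec50 = NULL),
  "quadratic" = list(fun = .quad, pars = c("b0", "b1", "b2"), poly = TRUE,
                     ec50 = NULL),
  "null" = list(fun = function(x) rep(0, length(x)), pars = character(0),
                poly = FALSE, ec50 = NULL)
)

#' Available dose-response families
#'
#' @param include_null Include the degenerate zero-response family used for
#'   inactive ground-truth curves.
#' @return Character vector of family names.
#' @export
dr_families <- function(include_null = FALSE) {
  nm <- names(.dr_families)
  if (!include_null) nm <- setdiff(nm, "null")
  nm
}

## Default candidate set for fitting/selection (the 2-parameter log-logistic
## has a fixed unit asymptote and is rarely appropriate for unbounded log2FC
## data; it is available but not a default candidate).
.default_families <- c("log-logistic-4", "log-logistic-3", "weibull-1",
                       "weibull-2", "michaelis-menten",
                       "asymptotic-regression", "gompertz",
                       "linear", "quadratic")

#' Construct a dose-response curve object
#'
#' Used both for fitted curves and for known ground-truth curves supplied to
#' the synthetic-data generator.
#'
#' @param family A family name from [dr_families()] (or `"null"` for an
#'   identically-zero curve).
#' @param params Named numeric vector of family parameters.
#' @param gene,treatment Optional identifiers.
#' @param direction `"up"`, `"down"` or `"flat"`; computed from the curve
#'   over `dose_range` when `NULL` and a range is given.
#' @param dose_range Doses over which to assess effect direction.
#' @param ... Further fields (`rss`, `n_obs`, `aic`, `ec50`, `converged`).
#' @return A `dr_curve` object.
#' @export
dr_curve <- function(family, params = numeric(0), gene = NA_character_,
                     treatment = NA_character_, direction = NULL,
                     dose_range = NULL, ...) {
  fam <- .dr_families[[family]]
  if (is.null(fam)) {
    stop("unknown dose-response family '", family, "'", call. = FALSE)
  }
  if (!setequal(names(params), fam$pars)) {
    stop(sprintf("family '%s' needs parameters {%s}, got {%s}", family,
                 paste(fam$pars, collapse = ","),
                 paste(names(params), collapse = ",")), call. = FALSE)
  }
  params <- params[fam$pars]
  obj <- structure(
    c(list(gene = gene, treatment = treatment, family = family,
           params = params, direction = direction), list(...)),
    class = "dr_curve")
  if (is.null(obj$converged)) obj$converged <- TRUE
  if (is.null(obj$direction)) {
    obj$direction <- if (!is.null(dose_range)) {
      curve_direction(obj, dose_range)
    } else NA_character_
  }
  obj
}

#' @export
print.dr_curve <- function(x, ...) {
  cat(sprintf("dr_curve [%s] %s/%s: %s\n", x$family,
              x$gene, x$treatment,
              paste(sprintf("%s=%.4g", names(x$params), x$params),
                    collapse = ", ")))
  if (!is.null(x$aic)) {
    cat(sprintf("  rss=%.4g aic=%.4g n=%d direction=%s ec50=%s\n",
                x$rss, x$aic, x$n_obs, x$direction,
                if (is.null(x$ec50) || is.na(x$ec50)) "-" else
                  format(x$ec50, digits = 4)))
  }
  invisible(x)
}

#' Evaluate the fitted mean of a curve at given doses
#'
#' @param curve A `dr_curve`.
#' @param doses Nonnegative doses (vehicle dose 0 allowed; log-dose families
#'   are evaluated through their dose-to-zero limits).
#' @return Numeric vector of modeled mean responses (log2FC units).
#' @export
evaluate_curve <- function(curve, doses) {
  stopifnot(inherits(curve, "dr_curve"))
  if (any(!is.finite(doses)) || any(doses < 0)) {
    stop("doses must be finite and nonnegative", call. = FALSE)
  }
  fam <- .dr_families[[curve$family]]
  do.call(fam$fun, c(list(x = doses), as.list(curve$params)))
}

#' Direction of effect of a curve over a dose range
#'
#' Sign of the modeled response of largest magnitude over the range; modeled
#' responses never exceeding `flat_threshold` (log2 units) in magnitude are
#' classified `"flat"`.
#'
#' @param curve A `dr_curve`.
#' @param dose_range Length-2 nonnegative dose range.
#' @param flat_threshold Magnitude below which the curve counts as flat.
#' @param n_grid Evaluation grid size.
#' @return `"up"`, `"down"` or `"flat"`.
#' @export
curve_direction <- function(curve, dose_range, flat_threshold = 0.1,
                            n_grid = 201L) {
  stopifnot(length(dose_range) == 2L, all(dose_range >= 0))
  grid <- unique(c(0, seq(min(dose_range), max(dose_range),
                          length.out = n_grid)))
  y <- evaluate_curve(curve, grid)
  m <- y[which.max(abs(y))]
  if (abs(m) < flat_threshold) "flat" else if (m > 0) "up" else "down"
}

## -- fitting -----------------------------------------------------------------

.fit_start <- function(doses, responses, fam_name) {
  # deterministic heuristic: c,d from response means at the dose extremes,
  # e from the dose bracketing the half response, multistart on b
  o <- order(doses)
  doses <- doses[o]; responses <- responses[o]
  c0 <- mean(responses[doses == min(doses)])
  d0 <- mean(responses[doses == max(doses)])
  if (abs(d0 - c0) < 1e-8) d0 <- c0 + ifelse(d0 >= c0, 0.5, -0.5)
  pos <- doses > 0
  half <- (c0 + d0) / 2
  e0 <- if (any(pos)) {
    agg <- tapply(responses[pos], doses[pos], mean)
    dd <- as.numeric(names(agg))
    dd[which.min(abs(agg - half))]
  } else 1
  if (!is.finite(e0) || e0 <= 0) e0 <- stats::median(doses[pos])
  list(c0 = c0, d0 = d0, e0 = e0)
}

.fit_nls_family <- function(doses, responses, fam_name, gene, treatment) {
  fam <- .dr_families[[fam_name]]
  s <- .fit_start(doses, responses, fam_name)
  b_starts <- c(-0.25, -0.5, -1, -2, -4)
  e_starts <- s$e0 * c(0.25, 0.5, 1, 2, 4)
  starts <- switch(
    fam_name,
    "log-logistic-4" = ,
    "weibull-1" = ,
    "weibull-2" = lapply(b_starts, function(b)
      list(b = b, c = s$c0, d = s$d0, e = s$e0)),
    "log-logistic-3" = lapply(b_starts, function(b)
      list(b = b, d = s$d0, e = s$e0)),
    "log-logistic-2" = lapply(b_starts, function(b)
      list(b = b, e = s$e0)),
    "gompertz" = lapply(b_starts / max(s$e0, 1e-6), function(b)
      list(b = b, c = s$c0, d = s$d0, e = s$e0)),
    "michaelis-menten" = ,
    "asymptotic-regression" = lapply(e_starts, function(e)
      list(c = s$c0, d = s$d0, e = e)),
    stop("no nls starts for family ", fam_name)
  )
  lower <- stats::setNames(rep(-Inf, length(fam$pars)), fam$pars)
  lower["e"] <- 1e-9
  dat <- data.frame(.x = doses, .y = responses)
  form <- stats::as.formula(paste0(
    ".y ~ .", switch(fam_name,
                     "log-logistic-4" = "ll4", "log-logistic-3" = "ll3",
                     "log-logistic-2" = "ll2", "weibull-1" = "w1",
                     "weibull-2" = "w2", "michaelis-menten" = "mm",
                     "asymptotic-regression" = "ar", "gompertz" = "gomp"),
    "(.x, ", paste(fam$pars, collapse = ", "), ")"))
  environment(form) <- asNamespace("pahmix")
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        form, data = dat, start = st, lower = lower[names(st)],
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(rss = rss, params = stats::coef(fit))
    }
  }
  best
}

.fit_poly_family <- function(doses, responses, fam_name) {
  fit <- if (fam_name == "linear") {
    stats::lm(responses ~ doses)
  } else {
    stats::lm(responses ~ doses + I(doses^2))
  }
  co <- unname(stats::coef(fit))
  params <- stats::setNames(co, .dr_families[[fam_name]]$pars)
  list(rss = sum(stats::resid(fit)^2), params = params)
}

#' Gaussian least-squares AIC of a fit
#'
#' `n * log(rss / n) + 2k` with `k = n_params + 1` (the residual variance
#' counts as a parameter). Additive constants of the Gaussian likelihood are
#' dropped consistently across families, so only AIC differences are
#' meaningful. The mean squared residual is floored at a tiny positive value
#' so exact fits keep a finite AIC.
#'
#' @param rss Residual sum of squares.
#' @param n Number of observations.
#' @param n_params Number of curve parameters.
#' @return AIC value.
#' @export
dr_aic <- function(rss, n, n_params) {
  n * log(max(rss / n, 1e-24)) + 2 * (n_params + 1)
}

#' Fit one dose-response family by least squares
#'
#' Nonlinear families are fit with Levenberg-Marquardt least squares using a
#' deterministic initialization heuristic plus a fixed 5-point multistart on
#' the slope (or location) parameter; polynomial families use ordinary linear
#' regression. Vehicle observations (dose 0) anchor the fits through the
#' families' dose-to-zero limits.
#'
#' @param doses Nonnegative doses (uM or BeP-equivalent uM), including dose 0.
#' @param responses log2 fold-change observations, same length.
#' @param family Family name from [dr_families()].
#' @param gene,treatment Optional identifiers stored on the result.
#' @param flat_threshold Passed to [curve_direction()].
#' @return A `dr_curve` with `rss`, `n_obs`, `aic`, `ec50` and `direction`
#'   fields; `converged = FALSE` (and no parameters) if no start converged.
#' @export
fit_family <- function(doses, responses, family, gene = NA_character_,
                       treatment = NA_character_, flat_threshold = 0.1) {
  fam <- .dr_families[[family]]
  if (is.null(fam) || family == "null") {
    stop("unknown or unfittable family '", family, "'", call. = FALSE)
  }
  keep <- is.finite(doses) & is.finite(responses)
  doses <- doses[keep]; responses <- responses[keep]
  if (any(doses < 0)) stop("doses must be nonnegative", call. = FALSE)
  n <- length(doses)
  if (n < length(fam$pars) + 1L) {
    stop(sprintf("family '%s' needs at least %d observations, got %d",
                 family, length(fam$pars) + 1L, n), call. = FALSE)
  }
  res <- if (fam$poly) {
    .fit_poly_family(doses, responses, family)
  } else {
    .fit_nls_family(doses, responses, family, gene, treatment)
  }
  if (is.null(res)) {
    return(structure(list(gene = gene, treatment = treatment,
                          family = family, params = NULL, rss = NA_real_,
                          n_obs = n, aic = NA_real_, ec50 = NA_real_,
                          direction = NA_character_, converged = FALSE),
                     class = "dr_curve"))
  }
  curve <- dr_curve(family, res$params, gene = gene, treatment = treatment,
                    dose_range = range(doses),
                    rss = res$rss, n_obs = n,
                    aic = dr_aic(res$rss, n, length(fam$pars)),
                    converged = TRUE,
                    dose_min = min(doses), dose_max = max(doses))
  curve$direction <- curve_direction(curve, range(doses), flat_threshold)
  curve$ec50 <- ec50(curve)
  curve
}

#' Fit a set of candidate families
#'
#' @inheritParams fit_family
#' @param families Character vector of family names (default: all standard
#'   saturating families plus linear and quadratic regression).
#' @return List of `dr_curve` objects (non-converged fits included, flagged).
#' @export
fit_all_families <- function(doses, responses, families = .default_families,
                             gene = NA_character_, treatment = NA_character_,
                             flat_threshold = 0.1) {
  out <- lapply(families, function(f) {
    n_min <- length(.dr_families[[f]]$pars) + 1L
    if (sum(is.finite(doses) & is.finite(responses)) < n_min) return(NULL)
    fit_family(doses, responses, f, gene, treatment, flat_threshold)
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Select the optimal model by AIC with the polynomial penalty rule
#'
#' The minimum-AIC candidate wins, except that a polynomial (linear or
#' quadratic) winner is only accepted when its AIC undercuts the best
#' saturating dose-response candidate by more than `margin` (default 2);
#' otherwise the best saturating candidate is returned.
#'
#' @param candidates List of `dr_curve` fits ([fit_all_families()] output).
#' @param margin AIC margin a polynomial must win by.
#' @return The selected `dr_curve`.
#' @export
select_model <- function(candidates, margin = 2) {
  if (inherits(candidates, "dr_curve")) candidates <- list(candidates)
  candidates <- Filter(function(x) isTRUE(x$converged), candidates)
  if (length(candidates) == 0L) {
    stop("no converged candidate fits to select from", call. = FALSE)
  }
  aics <- vapply(candidates, `[[`, numeric(1), "aic")
  poly <- vapply(candidates,
                 function(x) .dr_families[[x$family]]$poly, logical(1))
  best <- which.min(aics)
  if (!poly[best]) return(candidates[[best]])
  if (!any(!poly)) return(candidates[[best]])
  best_np <- which(!poly)[which.min(aics[!poly])]
  if (aics[best] < aics[best_np] - margin) {
    candidates[[best]]
  } else {
    candidates[[best_np]]
  }
}

#' Relative EC50 of a fitted curve
#'
#' The dose at which the modeled mean equals `c + (d - c) / 2`, i.e. half the
#' modeled span between the curve's asymptotes. Closed forms exist for every
#' saturating family in the registry; each is verified against bracketed
#' root-finding in the package tests. Polynomial and flat curves have no EC50
#' and return `NA` (not an error).
#'
#' @param curve A `dr_curve`.
#' @return EC50 on the curve's dose axis, or `NA_real_`.
#' @export
ec50 <- function(curve) {
  stopifnot(inherits(curve, "dr_curve"))
  fam <- .dr_families[[curve$family]]
  if (is.null(fam$ec50) || identical(curve$direction, "flat") ||
      !isTRUE(curve$converged)) {
    return(NA_real_)
  }
  val <- fam$ec50(curve$params)
  if (!is.finite(val) || val <= 0) NA_real_ else val
}
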