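# Independent-action model: identity, hand values, oracle equivalence,
# bounds, monotonicity, axis behavior.

test_that("a single active component reproduces its own curve exactly", {
  mix <- toxmix()
  set.seed(101)
  for (i in 1:20) {
    d <- runif(1, 0.5, 4) * sample(c(-1, 1), 1)
    e <- runif(1, 0.05, 5)
    b <- -runif(1, 0.5, 3)
    cm <- sample(mix$components$component, 1)
    curves <- stats::setNames(list(
      dr_curve("log-logistic-4", c(b = b, c = 0, d = d, e = e),
               direction = if (d > 0) "up" else "down")), cm)
    ctx <- build_context("G", curves, mix, axis = "uM",
                         dose_range = c(0.5, 10))
    doses <- c(0, 10^runif(5, -1, 1))
    pred <- ia_predict(ctx, doses)$grid$predicted
    direct <- evaluate_curve(curves[[cm]],
                             component_dose(mix, doses / 100, cm))
    expect_lt(max(abs(pred - direct)), 1e-12)
  }
})

test_that("hand-evaluated mixed and same-direction cases are reproduced", {
  # two up components at normalized effect 0.5 with direction maximum 2:
  # prediction (1 - 0.5^2) * 2 = 1.5
  mix <- two_comp_mix()
  curves <- list(A = dr_curve("linear", c(b0 = 0, b1 = 2), direction = "up"),
                 B = dr_curve("linear", c(b0 = 0, b1 = 2), direction = "up"))
  ctx <- build_context("G", curves, mix, axis = "uM", dose_range = c(0.01, 2))
  expect_equal(ctx$max_up, 2)  # component dose 1 at mixture dose 2
  expect_equal(ia_predict(ctx, 1)$grid$predicted, 1.5)
  # one up (E = +1 = max_up) plus one down (E = -2 = max_down): 1 - 2 = -1
  ctx2 <- const_ia_context(c(1, -2))
  expect_equal(ctx2$max_up, 1)
  expect_equal(ctx2$max_down, -2)
  pr <- ia_predict(ctx2, c(0.5, 5))
  expect_equal(pr$grid$predicted, c(-1, -1))
  expect_equal(pr$grid$up_term, c(1, 1))
  expect_equal(pr$grid$down_term, c(-2, -2))
  # all effects zero
  mix0 <- two_comp_mix()
  ctx0 <- build_context("G", list(A = NULL, B = NULL), mix0, axis = "uM",
                        dose_range = c(0.1, 10))
  expect_true(ctx0$empty)
  expect_equal(ia_predict(ctx0, c(1, 10))$grid$predicted, c(0, 0))
})

test_that("ia_predict matches the inclusion-exclusion brute-force oracle", {
  set.seed(202)
  for (rep in 1:25) {
    k <- sample(1:4, 1)
    effects <- runif(k, 0.05, 3)
    ctx <- const_ia_context(effects)
    pred <- ia_predict(ctx, 1)$grid$predicted
    u <- effects / max(effects)
    # brute-force expansion of 1 - prod(1 - u_i) by inclusion-exclusion
    combined <- 0
    for (m in seq_len(k)) {
      sets <- utils::combn(k, m, simplify = FALSE)
      combined <- combined + (-1)^(m + 1) *
        sum(vapply(sets, function(s) prod(u[s]), numeric(1)))
    }
    expect_lt(abs(pred - combined * max(effects)), 1e-12)
  }
})

test_that("per-direction terms respect their bounds for random contexts", {
  set.seed(303)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    effects <- runif(k, -3, 3)
    effects[abs(effects) < 0.2] <- 0.5  # keep away from the flat band
    ctx <- const_ia_context(effects)
    pr <- ia_predict(ctx, 10^runif(8, -1, 1))$grid
    expect_true(all(pr$up_term >= -1e-12 & pr$up_term <= ctx$max_up + 1e-12))
    expect_true(all(pr$down_term <= 1e-12 &
                      pr$down_term >= ctx$max_down - 1e-12))
    expect_equal(pr$predicted, pr$up_term + pr$down_term)
  }
})

test_that("increasing one normalized effect never decreases the up term", {
  base <- c(0.8, 1.5, 0.4)
  pred_at <- function(first_effect) {
    ctx <- const_ia_context(c(first_effect, base[-1]))
    ia_predict(ctx, 1)$grid$up_term
  }
  vals <- vapply(seq(0.15, 1.5, length.out = 12), pred_at, numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("effects beyond the directional maximum are clamped", {
  # constant curves cannot exceed their own max, so use a rising curve and a
  # narrow modeling range: extrapolating past the range exceeds max_up
  mix <- two_comp_mix()
  curves <- list(A = dr_curve("linear", c(b0 = 0, b1 = 1), direction = "up"),
                 B = NULL)
  ctx <- build_context("G", curves, mix, axis = "uM", dose_range = c(0.1, 2))
  expect_equal(ctx$max_up, 1)  # max over the modeled range
  pr <- ia_predict(ctx, 10)    # beyond the range: raw effect would be 5
  expect_equal(pr$grid$predicted, 1)  # clamped to max_up
})

test_that("ground-truth and fitted-curve kernels agree bitwise", {
  mix <- toxmix()
  truth <- study_truth(mix, genes = "CYP1A1")
  curves <- stats::setNames(
    lapply(mix$components$component, function(cm) {
      tc <- truth[[which(vapply(truth, function(t) t$treatment == cm,
                                logical(1)))]]
      if (identical(tc$family, "null")) NULL else tc
    }), mix$components$component)
  doses <- c(0.5, 1, 5, 10)
  via_truth <- ia_predict_from_truth(curves, mix, doses, axis = "uM",
                                     dose_range = c(0.5, 10))
  ctx <- build_context("CYP1A1", curves, mix, axis = "uM",
                       dose_range = c(0.5, 10))
  via_ctx <- ia_predict(ctx, doses)
  expect_identical(via_truth$grid$predicted, via_ctx$grid$predicted)
})

test_that("the literal product form breaks the single-component identity", {
  ctx <- const_ia_context(0.6)
  std <- ia_predict(ctx, 1)$grid$predicted
  lit <- ia_predict(ctx, 1, literal = TRUE)$grid$predicted
  expect_equal(std, 0.6)
  expect_false(isTRUE(all.equal(lit, 0.6)))
})

test_that("on the BeP-equivalent axis the highest-TEF component dominates", {
  # TEFs spanning three orders of magnitude: re-indexing by dose/TEF pushes
  # the low-TEF components far up their own curves, where they plateau at
  # their (sub-maximal) asymptotes; the prediction then varies essentially
  # with the high-TEF component alone and tracks its shape most closely
  mix <- mixture_definition("m3", data.frame(
    component = c("hiTEF", "midTEF", "loTEF"),
    proportion_percent = c(1, 9, 90),
    tef = c(1, 0.01, 0.001)), full_strength_total = 100)
  curves <- list(
    hiTEF = dr_curve("log-logistic-4", c(b = -1, c = 0, d = 3, e = 0.05),
                     direction = "up"),
    midTEF = dr_curve("log-logistic-4", c(b = -1, c = 0, d = 1, e = 0.045),
                      direction = "up"),
    loTEF = dr_curve("log-logistic-4", c(b = -1, c = 0, d = 1, e = 0.45),
                     direction = "up"))
  bep_range <- c(bep_equivalent(mix, 0.005), bep_equivalent(mix, 0.10))
  ctx <- build_context("G", curves, mix, axis = "bep",
                       dose_range = bep_range)
  grid <- dose_grid(bep_range, 50)
  pred <- ia_predict(ctx, grid)$grid$predicted
  cors <- vapply(names(curves), function(nm) {
    tef <- mix$components$tef[mix$components$component == nm]
    cor(pred, evaluate_curve(curves[[nm]], grid / tef))
  }, numeric(1))
  expect_identical(names(which.max(cors)), "hiTEF")
})

test_that("context building validates inputs and flags empty contexts", {
  mix <- two_comp_mix()
  expect_error(build_context("G", list(Z = const_curve(1)), mix,
                             axis = "uM", dose_range = c(1, 10)),
               "unknown components")
  # flat curves fall in neither direction set
  ctxf <- build_context("G", list(A = const_curve(0.01), B = NULL), mix,
                        axis = "uM", dose_range = c(1, 10))
  expect_true(ctxf$empty)
  expect_equal(ia_predict(ctxf, 5)$grid$predicted, 0)
})
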