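p0 <- default_parameters()
tm0 <- default_transition_model()

test_that("unknown parameters are rejected with the registered names", {
  expect_error(one_way("no_such_knob", p = p0, tm = tm0),
               "registered parameters.*prevalence_aneurysm")
  expect_true(all(c("start_age", "cta_sensitivity", "utility_favorable",
                    "cost_nursing_unfavorable_annual") %in%
                    registered_parameters()))
})

test_that("published ranges back the default sweeps", {
  expect_equal(default_range("start_age"), c(50, 80))
  expect_equal(default_range("prevalence_aneurysm"), c(0.05, 0.35))
  expect_equal(default_range("utility_favorable"), c(0.60, 1.00))
  expect_equal(default_range("cost_cta"), c(0.75 * 331, 1.25 * 331))
})

test_that("degenerate sweeps return identical records", {
  sw <- one_way("cost_cta", low = 331, high = 331, p = p0, tm = tm0)
  expect_equal(nrow(unique(sw[, -2])), 1)
})

test_that("sweeping a repeat-arm-only cost moves only that arm", {
  sw <- one_way("cost_cta", n_points = 5, p = p0, tm = tm0)
  expect_true(all(diff(sw$cost_repeat_cta) > 0))
  expect_equal(diff(range(sw$cost_no_repeat)), 0)
  expect_equal(diff(range(sw$delta_qaly)), 0)
  expect_true(all(diff(sw$nmb) < 0))
  # in the ICER regime the ICER itself rises with the intervention's cost
  p1 <- icer_regime_parameters()
  sw1 <- one_way("cost_cta", n_points = 5, p = p1, tm = tm0)
  expect_true(all(sw1$label == "icer"))
  expect_true(all(diff(sw1$icer) > 0))
})

test_that("simplex sweeps stay on the simplex", {
  sw <- one_way("outcome_rebleed_dead", low = 0.4, high = 0.8, n_points = 5,
                p = p0, tm = tm0)
  expect_equal(nrow(sw), 5)
  # the setter itself must renormalize
  p1 <- sahcea:::lookup_param("outcome_rebleed_dead")$set(p0, 0.8)
  expect_equal(sum(p1$outcome_rebleed), 1)
  expect_equal(p1$outcome_rebleed[["dead"]], 0.8)
  # no-aneurysm components keep their partner fixed, death takes the remainder
  p2 <- sahcea:::lookup_param("outcome_no_aneurysm_favorable")$set(p0, 0.80)
  expect_equal(p2$outcome_no_aneurysm[["unfavorable"]], 0.0792)
  expect_equal(sum(p2$outcome_no_aneurysm), 1)
})

test_that("a sweep evaluated at the base value reproduces the base case exactly", {
  base <- incremental_analysis(evaluate_strategy("no_repeat", p0, tm0),
                               evaluate_strategy("repeat_cta", p0, tm0))
  sw <- one_way("prevalence_aneurysm", low = 0.173, high = 0.35, n_points = 2,
                p = p0, tm = tm0)
  expect_identical(sw$cost_no_repeat[1], base$reference$expected_cost)
  expect_identical(sw$cost_repeat_cta[1], base$comparator$expected_cost)
  expect_identical(sw$qaly_repeat_cta[1], base$comparator$expected_qaly)
})

test_that("tornado bars are ordered by span and deterministic", {
  params <- c("utility_favorable", "cta_sensitivity", "cost_cta")
  t1 <- tornado(params, p = p0, tm = tm0)
  expect_equal(nrow(t1), 3)
  expect_true(all(diff(t1$span) <= 0))
  t2 <- tornado(params, p = p0, tm = tm0)
  expect_identical(t1, t2)

  single <- tornado("cost_cta", p = p0, tm = tm0)
  expect_equal(nrow(single), 1)

  # a pinned parameter has zero span and sorts last
  mixed <- tornado(list(utility_favorable = NULL, cost_cta = c(331, 331)),
                   p = p0, tm = tm0)
  expect_equal(mixed$parameter[nrow(mixed)], "cost_cta")
  expect_equal(mixed$span[nrow(mixed)], 0)
})

test_that("threshold search agrees with a fine sweep and reports direction", {
  p1 <- icer_regime_parameters()
  # pick a WTP between the ICERs at the bracket ends so a crossing exists
  ends <- sapply(c(0.05, 0.35), function(x) {
    sahcea:::evaluate_at("prevalence_aneurysm", x, p1, tm0)$icer
  })
  wtp <- mean(ends)
  ts <- threshold_search("prevalence_aneurysm", wtp = wtp,
                         bracket = c(0.05, 0.35), p = p1, tm = tm0)
  expect_equal(ts$status, "crossing")
  expect_false(ts$multiple)

  sw <- one_way("prevalence_aneurysm", low = 0.05, high = 0.35, n_points = 200,
                p = p1, tm = tm0, wtp = wtp)
  sign_flip <- which(diff(sign(sw$icer - wtp)) != 0)
  expect_length(sign_flip, 1)
  expect_gte(ts$crossing, sw$value[sign_flip])
  expect_lte(ts$crossing, sw$value[sign_flip + 1])
  # ICER falls as prevalence rises, so the repeat arm is cost-effective above
  expect_equal(ts$direction, "cost_effective_above")
})

test_that("a flat ICER yields no crossing", {
  ts <- threshold_search("cost_cta", wtp = 1e9, p = p0, tm = tm0)
  expect_equal(ts$status, "no crossing")
  expect_true(is.na(ts$crossing))
})
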