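p0 <- default_parameters()
tm0 <- default_transition_model()

test_that("hazard combination and discounting behave as closed forms", {
  expect_equal(combine_hazards(0, 0.3), 0.3)
  expect_equal(combine_hazards(1, 0.3), 1)
  expect_equal(combine_hazards(0.1, 0.2), 0.28)
  expect_equal(combine_hazards(0.1, 0.2), combine_hazards(0.2, 0.1))
  expect_true(combine_hazards(0.1, 0.2) >= 0.2)
  expect_error(combine_hazards(1.1, 0.2), "\\[0, 1\\]")

  expect_equal(discount_factor(0, 0.035), 1)
  expect_equal(discount_factor(5, 0), 1)
  expect_equal(discount_factor(2, 0.035), 1.035^-2)
})

test_that("re-bleed resolution mixes the emergency tariffs", {
  expect_equal(rebleed_resolution(p0)$cost, (19983.87 + 20275.02) / 2)
  p1 <- p0; p1$coiling_fraction <- 1
  expect_equal(rebleed_resolution(p1)$cost, 19983.87)
  out <- rebleed_resolution(p0)$outcome
  expect_equal(out[["favorable"]], 0.0752)
  expect_equal(out[["unfavorable"]], 0.3948)
  expect_equal(sum(out), 1)
})

test_that("short-term pathway resolves both arms' decision trees", {
  nr <- short_term_pathway("no_repeat", p0)
  expect_equal(nr$entry_mass[["at_risk"]], 0.173)
  expect_equal(nr$upfront_cost, 0)
  expect_equal(sum(nr$entry_mass), 1)

  rc <- short_term_pathway("repeat_cta", p0)
  expect_equal(rc$entry_mass[["at_risk"]], 0.173 * 0.02)
  expect_equal(sum(rc$entry_mass), 1)
  expect_equal(sum(rc$branch_log), 1)

  # perfect test leaves nobody at risk
  p1 <- p0; p1$cta_sensitivity <- 1
  expect_equal(short_term_pathway("repeat_cta", p1)$entry_mass[["at_risk"]], 0)

  # a cohort of pure true negatives pays exactly the stay plus the CTA
  p2 <- p0; p2$prevalence_aneurysm <- 0
  expect_equal(short_term_pathway("repeat_cta", p2)$upfront_cost,
               7 * 380.75 + 331)
})

test_that("an all-dead cohort accrues nothing", {
  tr <- run_cohort(single_state_entry("dead"), tm0, p0)
  expect_equal(attr(tr, "total_cost"), 0)
  expect_equal(attr(tr, "total_qaly"), 0)
})

test_that("single-state constant-hazard cohort matches the geometric series", {
  p <- p0
  p$state_mortality <- c(favorable = 0.1, unfavorable = 0, residual = 0.9)
  tm <- transition_model(zero_life_table(), zero_schedule())
  tr <- run_cohort(single_state_entry("favorable"), tm, p)
  T_ <- p$stop_age - p$start_age
  # terminal cycle forces death, so rewards run over cycles 1..T-1
  expected <- p$utility_favorable *
    sum(((1 - 0.1) / (1 + p$discount_qaly))^(seq_len(T_ - 1)))
  expect_equal(attr(tr, "total_qaly"), expected, tolerance = 1e-9)
})

test_that("one cycle in the unfavorable state accrues one discounted year of nursing", {
  p <- p0
  p$state_mortality <- c(favorable = 0.5, unfavorable = 0, residual = 0.5)
  tm <- transition_model(zero_life_table(), zero_schedule())
  tr <- run_cohort(single_state_entry("unfavorable"), tm, p)
  expect_equal(tr$cost[1], 84346.39 / 1.035, tolerance = 1e-12)
  expect_equal(tr$qaly[1], 0.44 / 1.035, tolerance = 1e-12)
})

test_that("traces conserve mass with death absorbing", {
  for (arm in c("no_repeat", "repeat_cta")) {
    r <- evaluate_strategy(arm, p0, tm0)
    expect_valid_trace(r$trace)
    expect_gte(r$expected_cost, r$upfront_cost)
  }
})

test_that("higher discount rates never increase totals", {
  totals <- sapply(c(0, 0.015, 0.035, 0.1), function(rate) {
    p <- p0; p$discount_qaly <- rate; p$discount_cost <- rate
    r <- evaluate_strategy("no_repeat", p, tm0)
    c(r$expected_cost, r$expected_qaly)
  })
  expect_true(all(diff(totals[1, ]) <= 1e-9))
  expect_true(all(diff(totals[2, ]) <= 1e-9))
})

test_that("repeat-arm QALY responds monotonically to CTA sensitivity", {
  qalys <- sapply(seq(0.2, 1, length.out = 5), function(s) {
    p <- p0; p$cta_sensitivity <- s
    evaluate_strategy("repeat_cta", p, tm0)$expected_qaly
  })
  d <- diff(qalys)
  expect_true(all(d >= -1e-9) || all(d <= 1e-9)) # monotone in sensitivity
  # and a better test is never worse for the cohort when treatment helps:
  # with a miserable at-risk state detection must raise QALYs
  p <- icer_regime_parameters()
  q <- sapply(c(0.2, 0.6, 0.98), function(s) {
    p$cta_sensitivity <- s
    evaluate_strategy("repeat_cta", p, tm0)$expected_qaly
  })
  expect_true(all(diff(q) > 0))
})

test_that("a useless test leaves only the upfront stay+CTA cost between arms", {
  p <- p0
  p$cta_sensitivity <- 0
  p$cta_specificity <- 1
  a <- evaluate_strategy("no_repeat", p, tm0)
  b <- evaluate_strategy("repeat_cta", p, tm0)
  expect_equal(b$expected_qaly, a$expected_qaly, tolerance = 1e-9)
  expect_equal(b$expected_cost - a$expected_cost,
               p$los_days * p$cost_hospital_day + p$cost_cta,
               tolerance = 1e-9)
})

test_that("half-cycle correction averages start and end occupancy", {
  p <- p0
  p$state_mortality <- c(favorable = 0.1, unfavorable = 0, residual = 0.9)
  tm <- transition_model(zero_life_table(), zero_schedule())
  p$half_cycle <- TRUE
  tr <- run_cohort(single_state_entry("favorable"), tm, p)
  # first cycle reward sits halfway between full entry mass and survivors
  expect_equal(tr$qaly[1], p$utility_favorable * (1 + 0.9) / 2 / 1.035,
               tolerance = 1e-12)
})

test_that("incremental analysis labels dominance and computes NMB", {
  a <- evaluate_strategy("no_repeat", p0, tm0)
  same <- incremental_analysis(a, a, wtp = 20000)
  expect_true(is.na(same$icer))
  expect_equal(same$label, "undefined")
  expect_equal(same$nmb, 0)

  mk <- function(cost, qaly) {
    r <- a; r$expected_cost <- cost; r$expected_qaly <- qaly; r
  }
  dom <- incremental_analysis(mk(100, 1), mk(50, 2), wtp = 20000)
  expect_equal(dom$label, "dominant")
  ddom <- incremental_analysis(mk(100, 2), mk(150, 1), wtp = 20000)
  expect_equal(ddom$label, "dominated")
  fin <- incremental_analysis(mk(100, 1), mk(300, 2), wtp = 20000)
  expect_equal(fin$icer, 200)
  expect_equal(fin$nmb, 20000 * 1 - 200)
})

test_that("matrix mode reproduces the equivalent state-mortality rule", {
  sm <- p0$state_mortality
  m <- data.frame(
    from = c("favorable", "favorable", "unfavorable", "unfavorable"),
    to = c("favorable", "dead", "unfavorable", "dead"),
    prob = c(1 - sm[["favorable"]], sm[["favorable"]],
             1 - sm[["unfavorable"]], sm[["unfavorable"]])
  )
  tm_m <- transition_model(tm0$life_table, tm0$rebleed_schedule, matrix = m)
  for (arm in c("no_repeat", "repeat_cta")) {
    a <- evaluate_strategy(arm, p0, tm0)
    b <- evaluate_strategy(arm, p0, tm_m)
    expect_equal(b$expected_cost, a$expected_cost)
    expect_equal(b$expected_qaly, a$expected_qaly)
  }
})

test_that("matrix mode supports favorable/unfavorable crossover", {
  m <- data.frame(
    from = c("favorable", "favorable", "favorable",
             "unfavorable", "unfavorable"),
    to = c("favorable", "unfavorable", "dead", "unfavorable", "dead"),
    prob = c(0.85, 0.05, 0.10, 0.3, 0.7)
  )
  tm_m <- transition_model(zero_life_table(), zero_schedule(), matrix = m)
  tr <- run_cohort(single_state_entry("favorable"), tm_m, p0)
  expect_equal(tr$unfavorable[1], 0.05)
  expect_equal(tr$favorable[1], 0.85)
  expect_equal(tr$dead[1], 0.10)
  expect_valid_trace(tr)
})
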