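# Shared fixtures for the test suite; everything is built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A life table with no background mortality until the closing age, so tests
# can isolate state-specific hazards.
zero_life_table <- function(cap = 200) {
  lt <- data.frame(age = 0:cap, qx = 0)
  lt$qx[nrow(lt)] <- 1
  lt
}

# A schedule with a single re-bleed probability in year 1 and nothing after.
one_shot_schedule <- function(prob = 0.5) {
  s <- data.frame(year = 1L, prob = prob)
  attr(s, "tail") <- "zero"
  s
}

zero_schedule <- function() one_shot_schedule(0)

# Entry profile placing the whole cohort in one state, no upfront cost.
single_state_entry <- function(state) {
  mass <- c(at_risk = 0, favorable = 0, unfavorable = 0, dead = 0)
  mass[state] <- 1
  structure(
    list(arm = "no_repeat", upfront_cost = 0, entry_mass = mass,
         branch_log = c(all = 1)),
    class = "entry_profile"
  )
}

# Trace invariant checks shared by unit and acceptance tests.
expect_valid_trace <- function(trace) {
  occ <- as.matrix(trace[, c("at_risk", "favorable", "unfavorable", "dead")])
  expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
  expect_true(all(diff(trace$dead) >= -1e-12))
  expect_true(all(trace$cost >= 0))
  expect_true(all(trace$qaly >= 0))
}

# A parameter set in which the at-risk state is grim enough that detecting
# and electively treating the aneurysm gains QALYs, so the comparison sits in
# the ICER regime; used by tests that need a finite willingness-to-pay
# crossing.
icer_regime_parameters <- function() {
  p <- default_parameters()
  p$utility_no_rebleed <- 0.10
  p
}
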