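state_names <- c("at_risk", "favorable", "unfavorable", "dead")

#' Combine a state-specific and a background annual death probability
#'
#' Treats the two risks as independent annual hazards:
#' `1 - (1 - p_state) * (1 - q_age)`. The result is symmetric in its
#' arguments and never below either input.
#'
#' @param p_state Annual excess death probability attached to a health state.
#' @param q_age Background all-cause death probability at the current age.
#' @return Combined annual death probability.
#' @export
combine_hazards <- function(p_state, q_age) {
  if (any(p_state < 0 | p_state > 1) || any(q_age < 0 | q_age > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  1 - (1 - p_state) * (1 - q_age)
}

#' Discount factor at a given cycle
#'
#' @param cycle Cycle index (0 = model entry, undiscounted).
#' @param rate Annual discount rate; must exceed -1.
#' @return `(1 + rate)^(-cycle)`.
#' @export
discount_factor <- function(cycle, rate) {
  if (any(rate <= -1)) stop("rate must exceed -1", call. = FALSE)
  (1 + rate)^(-cycle)
}

#' Emergency treatment cost and outcome split after a re-bleed
#'
#' A re-bleed triggers emergency aneurysm repair: the cost is the
#' coiling/clipping mix of the emergency tariffs, and survivors are
#' distributed over (favorable, unfavorable, dead) by the re-bleed outcome
#' vector, whose death share subsumes peri-procedural mortality.
#'
#' @param p A `parameter_set`.
#' @return A list with `cost` (GBP per re-bleed event) and `outcome`
#'   (probability 3-vector over favorable/unfavorable/dead).
#' @export
rebleed_resolution <- function(p) {
  cf <- p$coiling_fraction
  list(
    cost = cf * p$cost_emergency_coiling + (1 - cf) * p$cost_emergency_clipping,
    outcome = p$outcome_rebleed
  )
}

elective_cost <- function(p) {
  cf <- p$coiling_fraction
  cf * p$cost_elective_coiling + (1 - cf) * p$cost_elective_clipping
}

#' Short-term diagnostic pathway for one strategy arm
#'
#' Resolves the decision tree that precedes the Markov process and returns
#' an entry profile: the expected upfront cost incurred at model entry
#' (time 0, undiscounted) and the distribution of the cohort over the four
#' long-term health states.
#'
#' In the `no_repeat` arm, patients harboring an occult aneurysm
#' (`prevalence_aneurysm`) enter the at-risk state; the rest are distributed
#' by the no-aneurysm outcome vector. No upfront cost is incurred.
#'
#' In the `repeat_cta` arm, everyone accrues the 7-day observation stay plus
#' the repeat CTA. True positives additionally receive a confirmatory DSA and
#' elective repair (coiling/clipping mix) and enter per the elective outcome
#' vector; false negatives remain at risk; false positives receive a DSA
#' (which, as the reference standard with 100% specificity, rules them out)
#' and, like true negatives, follow the no-aneurysm outcome vector.
#'
#' @param arm `"no_repeat"` or `"repeat_cta"`.
#' @param p A `parameter_set`.
#' @return An object of class `entry_profile`: `upfront_cost`, `entry_mass`
#'   (named over at_risk/favorable/unfavorable/dead, summing to 1), and
#'   `branch_log` of labelled branch probabilities for audit.
#' @export
short_term_pathway <- function(arm = c("no_repeat", "repeat_cta"), p) {
  arm <- match.arg(arm)
  prev <- p$prevalence_aneurysm
  ona <- p$outcome_no_aneurysm
  if (arm == "no_repeat") {
    mass <- c(
      at_risk = prev,
      favorable = (1 - prev) * ona[["favorable"]],
      unfavorable = (1 - prev) * ona[["unfavorable"]],
      dead = (1 - prev) * ona[["dead"]]
    )
    profile <- list(
      arm = arm,
      upfront_cost = 0,
      entry_mass = mass,
      branch_log = c(aneurysm = prev, no_aneurysm = 1 - prev)
    )
  } else {
    tp <- prev * p$cta_sensitivity
    fn <- prev * (1 - p$cta_sensitivity)
    tn <- (1 - prev) * p$cta_specificity
    fp <- (1 - prev) * (1 - p$cta_specificity)
    oe <- p$outcome_elective
    stay <- p$los_days * p$cost_hospital_day
    upfront <- stay + p$cost_cta +         # everyone is observed and rescanned
      (tp + fp) * p$cost_dsa +             # CTA positives go to confirmatory DSA
      tp * elective_cost(p)                # confirmed aneurysms repaired electively
    mass <- c(
      at_risk = fn,
      favorable = tp * oe[["favorable"]] + (tn + fp) * ona[["favorable"]],
      unfavorable = tp * oe[["unfavorable"]] + (tn + fp) * ona[["unfavorable"]],
      dead = tp * oe[["dead"]] + (tn + fp) * ona[["dead"]]
    )
    profile <- list(
      arm = arm,
      upfront_cost = upfront,
      entry_mass = mass,
      branch_log = c(true_positive = tp, false_negative = fn,
                     true_negative = tn, false_positive = fp)
    )
  }
  stopifnot(abs(sum(profile$entry_mass) - 1) < 1e-9)
  structure(profile, class = "entry_profile")
}

#' Transition model: life table, re-bleed schedule and long-term movement rules
#'
#' Bundles everything the Markov engine needs beyond the parameter set:
#' the background-mortality life table, the years-since-presentation annual
#' re-bleed schedule, and the movement rule for the favorable/unfavorable
#' states. In the default `"state_mortality"` mode the annual death
#' probabilities of the favorable and unfavorable states are read from
#' `ParameterSet$state_mortality` at run time and no favorable/unfavorable
#' crossover occurs; in `"matrix"` mode a full from/to/prob annual transition
#' matrix (e.g. loaded with [read_transition_matrix()]) overrides this.
#' State-specific death is always combined with the age-indexed life-table
#' probability via [combine_hazards()].
#'
#' @param life_table Data frame with columns `age`, `qx`
#'   (see [gompertz_life_table()]).
#' @param rebleed_schedule Data frame with columns `year`, `prob` plus a
#'   `tail` attribute (see [default_rebleed_schedule()]).
#' @param matrix Optional transition matrix data frame (`from`, `to`, `prob`)
#'   over the favorable/unfavorable/dead states; switches the model to
#'   `"matrix"` mode.
#' @return An object of class `transition_model`.
#' @export
transition_model <- function(life_table = gompertz_life_table(),
                             rebleed_schedule = default_rebleed_schedule(),
                             matrix = NULL) {
  check_life_table(life_table)
  check_rebleed_schedule(rebleed_schedule)
  mode <- if (is.null(matrix)) "state_mortality" else "matrix"
  if (!is.null(matrix)) check_transition_matrix(matrix)
  structure(
    list(life_table = life_table, rebleed_schedule = rebleed_schedule,
         mode = mode, matrix = matrix, combination = "independent_hazards"),
    class = "transition_model"
  )
}

lt_qx <- function(life_table, age) {
  idx <- findInterval(age, life_table$age)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(life_table)] <- nrow(life_table)
  life_table$qx[idx]
}

schedule_prob <- function(sched, year) {
  tail_rule <- attr(sched, "tail")
  if (is.null(tail_rule)) tail_rule <- "constant"
  hit <- match(year, sched$year)
  if (!is.na(hit)) return(sched$prob[hit])
  if (year > max(sched$year)) {
    if (tail_rule == "constant") sched$prob[which.max(sched$year)] else 0
  } else {
    0 # years before the schedule starts carry no re-bleed risk
  }
}

# Annual movement rule for the favorable/unfavorable states: returns, for the
# current age, each state's combined death probability and (matrix mode only)
# the crossover probabilities among survivors.
survivor_rule <- function(tm, p, q) {
  if (tm$mode == "state_mortality") {
    list(
      die_fav = combine_hazards(p$state_mortality[["favorable"]], q),
      die_unf = combine_hazards(p$state_mortality[["unfavorable"]], q),
      fav_to_unf = 0, unf_to_fav = 0
    )
  } else {
    m <- tm$matrix
    pr <- function(from, to) {
      hit <- m$prob[m$from == from & m$to == to]
      if (length(hit)) hit[[1L]] else 0
    }
    die_fav <- combine_hazards(pr("favorable", "dead"), q)
    die_unf <- combine_hazards(pr("unfavorable", "dead"), q)
    # survivors split between the two living states in the matrix's proportions
    f_stay <- pr("favorable", "favorable"); f_cross <- pr("favorable", "unfavorable")
    u_stay <- pr("unfavorable", "unfavorable"); u_cross <- pr("unfavorable", "favorable")
    f_tot <- f_stay + f_cross
    u_tot <- u_stay + u_cross
    list(
      die_fav = die_fav,
      die_unf = die_unf,
      fav_to_unf = if (f_tot > 0) f_cross / f_tot else 0,
      unf_to_fav = if (u_tot > 0) u_cross / u_tot else 0
    )
  }
}

#' Run the Markov cohort engine
#'
#' Propagates the cohort's state occupancy one-year cycle at a time from the
#' entry profile to the end of the horizon, accruing discounted costs and
#' QALYs.
#'
#' Per cycle, at-risk patients re-bleed with the years-since-presentation
#' schedule probability (the moving mass is split by [rebleed_resolution()],
#' accrues the emergency cost, and survivors enter their outcome state in the
#' same cycle, earning that state's reward); otherwise they die at the
#' background life-table rate or stay. Favorable/unfavorable patients die at
#' the combined state + background rate or move per the transition model.
#' Death absorbs. State rewards (utilities; annual nursing cost for the
#' unfavorable state) accrue on end-of-cycle occupancy at discount exponent
#' equal to the cycle index; with `half_cycle = TRUE` the state rewards use
#' the mean of start- and end-of-cycle occupancy instead. The terminal cycle
#' forces the background death probability to 1 so the horizon closes; the
#' run also stops once living mass falls below 1e-9.
#'
#' @param entry An `entry_profile` from [short_term_pathway()].
#' @param tm A `transition_model`.
#' @param p A `parameter_set`.
#' @param start_age,stop_age Cohort age at entry and horizon close
#'   (defaults from `p`).
#' @return A `cea_trace` data frame with one row per executed cycle (cycle,
#'   age, the four state occupancies, re-bleed mass, discounted cost and QALY
#'   accruals) and attributes `total_cost`, `total_qaly` (Markov part only,
#'   excluding the upfront cost).
#' @export
run_cohort <- function(entry, tm, p, start_age = p$start_age,
                       stop_age = p$stop_age) {
  stopifnot(inherits(entry, "entry_profile"), inherits(tm, "transition_model"))
  if (start_age >= stop_age) stop("start_age must be below stop_age", call. = FALSE)
  n_cycles <- as.integer(ceiling(stop_age - start_age))
  res <- rebleed_resolution(p)
  orb <- res$outcome
  u <- c(at_risk = p$utility_no_rebleed, favorable = p$utility_favorable,
         unfavorable = p$utility_unfavorable, dead = p$utility_dead)

  o <- entry$entry_mass[state_names]
  cyc <- age_v <- cost_v <- qaly_v <- reb_v <- numeric(n_cycles)
  occ <- matrix(0, n_cycles, 4L, dimnames = list(NULL, state_names))
  used <- 0L
  for (t in seq_len(n_cycles)) {
    age <- start_age + t - 1
    q <- if (t == n_cycles) 1 else lt_qx(tm$life_table, age)
    r <- schedule_prob(tm$rebleed_schedule, t)
    rule <- survivor_rule(tm, p, q)

    rebleed_mass <- o[["at_risk"]] * r
    ar_stay <- o[["at_risk"]] * (1 - r) * (1 - q)
    fav_surv <- o[["favorable"]] * (1 - rule$die_fav)
    unf_surv <- o[["unfavorable"]] * (1 - rule$die_unf)
    new <- c(
      at_risk = ar_stay,
      favorable = fav_surv * (1 - rule$fav_to_unf) + unf_surv * rule$unf_to_fav +
        rebleed_mass * orb[["favorable"]],
      unfavorable = unf_surv * (1 - rule$unf_to_fav) + fav_surv * rule$fav_to_unf +
        rebleed_mass * orb[["unfavorable"]],
      dead = 0
    )
    # dead is the complement of the living mass; total mass is conserved at 1
    new[["dead"]] <- 1 - sum(new[c("at_risk", "favorable", "unfavorable")])
    reward_occ <- if (isTRUE(p$half_cycle)) (o + new) / 2 else new
    dq <- discount_factor(t, p$discount_qaly)
    dc <- discount_factor(t, p$discount_cost)
    qaly_v[t] <- sum(reward_occ * u) * dq
    cost_v[t] <- (reward_occ[["unfavorable"]] * p$cost_nursing_unfavorable_annual +
                    rebleed_mass * res$cost) * dc
    cyc[t] <- t; age_v[t] <- age; reb_v[t] <- rebleed_mass
    occ[t, ] <- new
    o <- new
    used <- t
    if (sum(o[c("at_risk", "favorable", "unfavorable")]) < 1e-9) break
  }
  keep <- seq_len(used)
  trace <- data.frame(
    cycle = cyc[keep], age = age_v[keep], occ[keep, , drop = FALSE],
    rebleed_mass = reb_v[keep], cost = cost_v[keep], qaly = qaly_v[keep]
  )
  attr(trace, "total_cost") <- sum(cost_v[keep])
  attr(trace, "total_qaly") <- sum(qaly_v[keep])
  attr(trace, "start_age") <- start_age
  class(trace) <- c("cea_trace", "data.frame")
  trace
}

#' Evaluate one strategy end to end
#'
#' Composes [short_term_pathway()] and [run_cohort()]: the decision-tree
#' upfront cost is incurred undiscounted at time 0 and the Markov accruals
#' follow over the lifetime horizon.
#'
#' @inheritParams run_cohort
#' @param arm `"no_repeat"` or `"repeat_cta"`.
#' @return An object of class `strategy_result` with `strategy`,
#'   `expected_cost`, `expected_qaly`, `upfront_cost`, the `entry_profile`
#'   and the full `trace`.
#' @export
evaluate_strategy <- function(arm, p, tm) {
  entry <- short_term_pathway(arm, p)
  trace <- run_cohort(entry, tm, p)
  structure(
    list(
      strategy = arm,
      expected_cost = entry$upfront_cost + attr(trace, "total_cost"),
      expected_qaly = attr(trace, "total_qaly"),
      upfront_cost = entry$upfront_cost,
      entry = entry,
      trace = trace
    ),
    class = "strategy_result"
  )
}

strategy_result <- function(strategy, expected_cost, expected_qaly,
                            upfront_cost = 0, trace = NULL, entry = NULL) {
  structure(
    list(strategy = strategy, expected_cost = expected_cost,
         expected_qaly = expected_qaly, upfront_cost = upfront_cost,
         entry = entry, trace = trace),
    class = "strategy_result"
  )
}

#' Incremental cost-effectiveness comparison of two strategies
#'
#' @param ref Reference `strategy_result` (here: no repeat imaging).
#' @param comp Comparator `strategy_result` (here: repeat delayed CTA).
#' @param wtp Willingness-to-pay threshold in GBP per QALY for the net
#'   monetary benefit.
#' @return An object of class `ce_comparison`: `delta_cost`, `delta_qaly`,
#'   `icer` (`NA` when `delta_qaly` is 0), a `label` in
#'   `{"icer", "dominant", "dominated", "undefined"}` taken from the
#'   comparator's perspective, and `nmb = wtp * delta_qaly - delta_cost`.
#' @export
incremental_analysis <- function(ref, comp, wtp = 20000) {
  stopifnot(inherits(ref, "strategy_result"), inherits(comp, "strategy_result"))
  dc <- comp$expected_cost - ref$expected_cost
  dq <- comp$expected_qaly - ref$expected_qaly
  icer <- if (dq != 0) dc / dq else NA_real_
  label <- if (dc < 0 && dq > 0) {
    "dominant"
  } else if (dc > 0 && dq < 0) {
    "dominated"
  } else if (dq == 0) {
    "undefined"
  } else {
    "icer"
  }
  structure(
    list(reference = ref, comparator = comp,
         delta_cost = dc, delta_qaly = dq, icer = icer, label = label,
         wtp = wtp, nmb = wtp * dq - dc),
    class = "ce_comparison"
  )
}

#' Write a Markov trace to CSV
#'
#' @param trace A `cea_trace` from [run_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result> %s: cost £%.2f, effectiveness %.3f QALY\n",
              x$strategy, x$expected_cost, x$expected_qaly))
  invisible(x)
}

#' @export
print.ce_comparison <- function(x, ...) {
  cat("<ce_comparison>\n")
  cat(sprintf("  %-28s £%10.2f  %6.3f QALY\n", x$reference$strategy,
              x$reference$expected_cost, x$reference$expected_qaly))
  cat(sprintf("  %-28s £%10.2f  %6.3f QALY\n", x$comparator$strategy,
              x$comparator$expected_cost, x$comparator$expected_qaly))
  cat(sprintf("  incremental: £%.2f, %.3f QALY\n", x$delta_cost, x$delta_qaly))
  if (x$label == "icer") {
    cat(sprintf("  ICER: £%.0f per QALY (NMB at £%s/QALY: £%.2f)\n",
                x$icer, format(x$wtp, big.mark = ","), x$nmb))
  } else {
    cat(sprintf("  comparator is %s (NMB at £%s/QALY: £%.2f)\n",
                x$label, format(x$wtp, big.mark = ","), x$nmb))
  }
  invisible(x)
}
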