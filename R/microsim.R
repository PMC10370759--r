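#' Individual-level microsimulation oracle
#'
#' Re-derives a strategy's expected discounted cost and QALY by simulating
#' individual patient trajectories instead of propagating cohort fractions.
#' Every decision-tree branch (aneurysm status, test result, treatment
#' outcome) and every annual transition is sampled directly, under the same
#' accounting conventions as [run_cohort()]: upfront costs at time 0
#' undiscounted, state rewards on the end-of-cycle state at discount
#' exponent equal to the cycle index, emergency re-bleed cost in the cycle
#' the re-bleed occurs, survivors of a re-bleed earning their outcome
#' state's reward that same cycle. It is used to validate the cohort engine,
#' to which it must agree within Monte-Carlo error.
#'
#' The half-cycle corrected convention is not simulated; request it from the
#' cohort engine only.
#'
#' @param arm `"no_repeat"` or `"repeat_cta"`.
#' @param p A `parameter_set`.
#' @param tm A `transition_model`.
#' @param n_individuals Number of simulated patients.
#' @param seed Integer seed for the simulation's own RNG stream (kept
#'   independent of any PSA stream via a local [set.seed()]).
#' @return A `strategy_result` whose `expected_cost` / `expected_qaly` are
#'   sample means, with additional fields `se_cost`, `se_qaly` and
#'   `n_individuals`.
#' @export
microsim_oracle <- function(arm = c("no_repeat", "repeat_cta"), p, tm,
                            n_individuals = 200000, seed = 1) {
  arm <- match.arg(arm)
  stopifnot(n_individuals >= 1)
  if (isTRUE(p$half_cycle)) {
    stop("microsim_oracle checks the default (end-of-cycle) convention only",
         call. = FALSE)
  }
  n <- as.integer(n_individuals)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  S_ATRISK <- 1L; S_FAV <- 2L; S_UNF <- 3L; S_DEAD <- 4L
  res <- rebleed_resolution(p)
  cum_orb <- cumsum(res$outcome)
  ona <- p$outcome_no_aneurysm
  cum_ona <- cumsum(ona)
  oe <- p$outcome_elective
  cum_oe <- cumsum(oe)
  draw_state <- function(k, cum) {
    u <- stats::runif(k)
    ifelse(u < cum[1L], S_FAV, ifelse(u < cum[2L], S_UNF, S_DEAD))
  }

  cost <- numeric(n)
  qaly <- numeric(n)

  # --- decision tree ---
  has_aneurysm <- stats::runif(n) < p$prevalence_aneurysm
  state <- integer(n)
  if (arm == "no_repeat") {
    state[has_aneurysm] <- S_ATRISK
    state[!has_aneurysm] <- draw_state(sum(!has_aneurysm), cum_ona)
  } else {
    detected <- logical(n)
    detected[has_aneurysm] <- stats::runif(sum(has_aneurysm)) < p$cta_sensitivity
    flagged <- logical(n) # CTA-positive among the aneurysm-free
    flagged[!has_aneurysm] <- stats::runif(sum(!has_aneurysm)) >= p$cta_specificity
    cost <- cost + p$los_days * p$cost_hospital_day + p$cost_cta
    tp <- has_aneurysm & detected
    fn <- has_aneurysm & !detected
    fp <- !has_aneurysm & flagged
    cost[tp | fp] <- cost[tp | fp] + p$cost_dsa
    cost[tp] <- cost[tp] + elective_cost(p)
    state[tp] <- draw_state(sum(tp), cum_oe)
    state[fn] <- S_ATRISK
    state[!has_aneurysm] <- draw_state(sum(!has_aneurysm), cum_ona)
  }

  # --- Markov process ---
  u_state <- c(p$utility_no_rebleed, p$utility_favorable, p$utility_unfavorable,
               p$utility_dead)
  start_age <- p$start_age
  n_cycles <- as.integer(ceiling(p$stop_age - start_age))
  for (t in seq_len(n_cycles)) {
    alive <- state != S_DEAD
    if (!any(alive)) break
    age <- start_age + t - 1
    q <- if (t == n_cycles) 1 else lt_qx(tm$life_table, age)
    r <- schedule_prob(tm$rebleed_schedule, t)
    rule <- survivor_rule(tm, p, q)
    dq <- discount_factor(t, p$discount_qaly)
    dc <- discount_factor(t, p$discount_cost)

    idx <- which(alive)
    st <- state[idx]
    u1 <- stats::runif(length(idx))

    ar <- st == S_ATRISK
    rebleed <- ar & (u1 < r)
    if (any(rebleed)) {
      k <- which(rebleed)
      cost[idx[k]] <- cost[idx[k]] + res$cost * dc
      st[k] <- draw_state(length(k), cum_orb)
    }
    ar_no <- ar & !rebleed
    if (any(ar_no)) {
      k <- which(ar_no)
      # rescale the residual uniform so the death draw stays independent
      died <- (u1[k] - r) / (1 - r) < q
      st[k][died] <- S_DEAD
    }
    fav <- st == S_FAV & !rebleed
    if (any(fav)) {
      k <- which(fav)
      u2 <- stats::runif(length(k))
      died <- u2 < rule$die_fav
      crossed <- !died & (stats::runif(length(k)) < rule$fav_to_unf)
      st[k][died] <- S_DEAD
      st[k][crossed] <- S_UNF
    }
    unf <- st == S_UNF & !rebleed
    if (any(unf)) {
      k <- which(unf)
      u2 <- stats::runif(length(k))
      died <- u2 < rule$die_unf
      crossed <- !died & (stats::runif(length(k)) < rule$unf_to_fav)
      st[k][died] <- S_DEAD
      st[k][crossed] <- S_FAV
    }
    state[idx] <- st
    qaly[idx] <- qaly[idx] + u_state[st] * dq
    nursing <- idx[st == S_UNF]
    cost[nursing] <- cost[nursing] + p$cost_nursing_unfavorable_annual * dc
  }

  out <- strategy_result(
    strategy = arm,
    expected_cost = mean(cost),
    expected_qaly = mean(qaly)
  )
  out$se_cost <- stats::sd(cost) / sqrt(n)
  out$se_qaly <- stats::sd(qaly) / sqrt(n)
  out$n_individuals <- n
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
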