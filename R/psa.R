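rdirichlet1 <- function(conc) {
  repeat {
    g <- stats::rgamma(length(conc), shape = conc, rate = 1)
    s <- sum(g)
    if (s > 0) return(g / s)
  }
}

draw_dist <- function(d) {
  p <- d$params
  switch(d$family,
    beta = stats::rbeta(1, p$alpha, p$beta),
    gamma = stats::rgamma(1, shape = p$shape, rate = p$rate),
    dirichlet = rdirichlet1(p$concentration),
    point = p$value
  )
}

#' Draw one parameter set from the PSA distributions
#'
#' Samples every field that carries a distribution specification — Beta for
#' probabilities and utilities, Gamma for costs, Dirichlet jointly for each
#' outcome vector — and leaves everything else (age, discount rates, length
#' of stay, the no-re-bleed utility) at its base value. Draws are consumed
#' from the current RNG stream in a fixed field order (the order of the
#' `dist` map), so results are reproducible given a seed.
#'
#' Two composite rules mirror the structure of the inputs: the
#' favorable/unfavorable probabilities of the no-aneurysm outcome are drawn
#' from their own Beta specifications with death as the remainder (the pair
#' is redrawn in the vanishingly rare case it exceeds 1), and the hospital
#' stay is drawn as the whole-admission cost block, the per-day cost being
#' the block divided by the length of stay.
#'
#' @param p A `parameter_set` whose `dist` map defines the draws.
#' @return A new `parameter_set` with sampled values (its `dist` map is kept
#'   unchanged).
#' @export
sample_parameter_set <- function(p) {
  out <- p
  for (nm in names(p$dist)) {
    d <- p$dist[[nm]]
    if (nm == "outcome_no_aneurysm_favorable") {
      next # drawn jointly when its unfavorable partner comes up
    }
    if (nm == "outcome_no_aneurysm_unfavorable") {
      dfav <- p$dist[["outcome_no_aneurysm_favorable"]]
      repeat {
        fav <- draw_dist(dfav)
        unf <- draw_dist(d)
        if (fav + unf <= 1) break
      }
      out$outcome_no_aneurysm <- c(favorable = fav, unfavorable = unf,
                                   dead = 1 - fav - unf)
    } else if (nm == "cost_hospital_stay_total") {
      out$cost_hospital_day <- draw_dist(d) / p$los_days
    } else if (nm %in% c("outcome_rebleed", "outcome_elective", "state_mortality")) {
      x <- draw_dist(d)
      names(x) <- names(p[[nm]])
      out[[nm]] <- x
    } else {
      out[[nm]] <- draw_dist(d)
    }
  }
  out
}

#' Run a probabilistic sensitivity analysis
#'
#' Draws `n` parameter sets with [sample_parameter_set()] and evaluates both
#' strategies on each draw (the same draw is used for both arms, so common
#' parameters are shared).
#'
#' @param p A `parameter_set`.
#' @param tm A `transition_model`.
#' @param n Number of Monte Carlo iterations (default 5000).
#' @param seed Integer seed; the whole run is reproducible from it.
#' @return An object of class `psa_result`: `n`, `seed` and a `draws` data
#'   frame with per-iteration costs and QALYs for both strategies.
#' @export
run_psa <- function(p, tm = default_transition_model(), n = 5000, seed = 1) {
  stopifnot(n >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cost_nr <- qaly_nr <- cost_rc <- qaly_rc <- numeric(n)
  for (i in seq_len(n)) {
    ps <- sample_parameter_set(p)
    res <- tryCatch(
      {
        a <- evaluate_strategy("no_repeat", ps, tm)
        b <- evaluate_strategy("repeat_cta", ps, tm)
        list(a = a, b = b)
      },
      error = function(e) {
        stop(sprintf("PSA draw %d failed (%s); prevalence=%.4g sens=%.4g",
                     i, conditionMessage(e), ps$prevalence_aneurysm,
                     ps$cta_sensitivity), call. = FALSE)
      }
    )
    cost_nr[i] <- res$a$expected_cost; qaly_nr[i] <- res$a$expected_qaly
    cost_rc[i] <- res$b$expected_cost; qaly_rc[i] <- res$b$expected_qaly
  }
  structure(
    list(
      n = n, seed = seed,
      draws = data.frame(
        iteration = seq_len(n),
        cost_no_repeat = cost_nr, qaly_no_repeat = qaly_nr,
        cost_repeat_cta = cost_rc, qaly_repeat_cta = qaly_rc
      )
    ),
    class = "psa_result"
  )
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, computes the probability that each
#' strategy is cost-effective: the fraction of iterations in which it has
#' the strictly larger net monetary benefit, ties split equally. The two
#' probabilities sum to 1 at every threshold.
#'
#' @param r A `psa_result`.
#' @param wtp_grid Willingness-to-pay grid in GBP/QALY (default 0 to 50,000
#'   in steps of 1,000).
#' @return A `ceac_curve` data frame: `wtp`, `p_no_repeat`, `p_repeat_cta`.
#' @export
ceac <- function(r, wtp_grid = seq(0, 50000, by = 1000)) {
  stopifnot(inherits(r, "psa_result"), length(wtp_grid) >= 1)
  d <- r$draws
  rows <- vapply(wtp_grid, function(w) {
    nmb_nr <- w * d$qaly_no_repeat - d$cost_no_repeat
    nmb_rc <- w * d$qaly_repeat_cta - d$cost_repeat_cta
    mean((nmb_rc > nmb_nr) + 0.5 * (nmb_rc == nmb_nr))
  }, numeric(1))
  out <- data.frame(wtp = wtp_grid, p_no_repeat = 1 - rows, p_repeat_cta = rows)
  class(out) <- c("ceac_curve", "data.frame")
  out
}

#' Summarize a PSA at one willingness-to-pay threshold
#'
#' @param r A `psa_result`.
#' @param wtp Willingness-to-pay threshold (GBP/QALY).
#' @return A list: `wtp`, `p_repeat_cost_effective` (the CEAC read-out at
#'   `wtp`), and per-strategy means and 95% credible intervals (2.5/97.5
#'   percentiles) of cost and QALY.
#' @export
psa_summary <- function(r, wtp = 20000) {
  stopifnot(inherits(r, "psa_result"))
  d <- r$draws
  ci <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  strat <- function(cost, qaly) {
    list(mean_cost = mean(cost), ci_cost = ci(cost),
         mean_qaly = mean(qaly), ci_qaly = ci(qaly))
  }
  list(
    wtp = wtp,
    n = r$n,
    p_repeat_cost_effective = ceac(r, wtp)$p_repeat_cta,
    no_repeat = strat(d$cost_no_repeat, d$qaly_no_repeat),
    repeat_cta = strat(d$cost_repeat_cta, d$qaly_repeat_cta)
  )
}

#' @export
print.psa_result <- function(x, ...) {
  s <- psa_summary(x)
  cat(sprintf("<psa_result> %d iterations (seed %d)\n", x$n, x$seed))
  cat(sprintf("  P(repeat CTA cost-effective at £20,000/QALY) = %.4f\n",
              s$p_repeat_cost_effective))
  invisible(x)
}
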