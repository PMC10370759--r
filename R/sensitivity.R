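# Registry of sweepable scalar parameters. Each entry knows how to read the
# value from a parameter_set, how to write it back (simplex components
# rescale their siblings so rows stay on the simplex; the no-aneurysm outcome
# keeps its printed favorable/unfavorable values independent, with death as
# the remainder), and its default one-way range (published range where one
# exists, otherwise +/-25% of base).

set_simplex_component <- function(vec, i, x) {
  if (is.character(i)) i <- match(i, names(vec))
  if (x < 0 || x > 1) stop("simplex component outside [0, 1]", call. = FALSE)
  others <- vec[-i]
  rest <- sum(others)
  vec[-i] <- if (rest > 0) others * (1 - x) / rest else (1 - x) / length(others)
  vec[i] <- x
  vec
}

set_remainder_component <- function(p, field, component, x) {
  vec <- p[[field]]
  vec[[component]] <- x
  vec[["dead"]] <- 1 - sum(vec[setdiff(names(vec), "dead")])
  if (vec[["dead"]] < -1e-12) {
    stop(sprintf("%s: living outcomes exceed 1", field), call. = FALSE)
  }
  vec[["dead"]] <- max(vec[["dead"]], 0)
  p[[field]] <- vec
  p
}

pct25 <- function(x) c(0.75 * x, 1.25 * x)

param_registry <- function() {
  scalar <- function(field, range_fn) {
    list(
      get = function(p) p[[field]],
      set = function(p, x) { p[[field]] <- x; p },
      range = range_fn
    )
  }
  simplex <- function(field, comp) {
    i <- comp
    list(
      get = function(p) p[[field]][[i]],
      set = function(p, x) { p[[field]] <- set_simplex_component(p[[field]], i, x); p },
      range = function(p) {
        x <- p[[field]][[i]]
        c(max(0, 0.75 * x), min(1, 1.25 * x))
      }
    )
  }
  remainder <- function(field, comp, range_fn) {
    list(
      get = function(p) p[[field]][[comp]],
      set = function(p, x) set_remainder_component(p, field, comp, x),
      range = range_fn
    )
  }
  list(
    start_age = scalar("start_age", function(p) c(50, 80)),
    prevalence_aneurysm = scalar("prevalence_aneurysm", function(p) c(0.05, 0.35)),
    cta_sensitivity = scalar("cta_sensitivity", function(p) c(0.20, 0.99)),
    cta_specificity = scalar("cta_specificity", function(p) c(0.20, 1.00)),
    outcome_no_aneurysm_favorable =
      remainder("outcome_no_aneurysm", "favorable", function(p) c(0.8030, 0.9160)),
    outcome_no_aneurysm_unfavorable =
      remainder("outcome_no_aneurysm", "unfavorable", function(p) c(0.0791, 0.0793)),
    outcome_rebleed_favorable = simplex("outcome_rebleed", "favorable"),
    outcome_rebleed_unfavorable = simplex("outcome_rebleed", "unfavorable"),
    outcome_rebleed_dead = simplex("outcome_rebleed", "dead"),
    outcome_elective_favorable = simplex("outcome_elective", "favorable"),
    outcome_elective_dead = simplex("outcome_elective", "dead"),
    state_mortality_favorable = simplex("state_mortality", "favorable"),
    state_mortality_unfavorable = simplex("state_mortality", "unfavorable"),
    cost_cta = scalar("cost_cta", function(p) pct25(p$cost_cta)),
    cost_dsa = scalar("cost_dsa", function(p) pct25(p$cost_dsa)),
    cost_hospital_day = scalar("cost_hospital_day", function(p) pct25(p$cost_hospital_day)),
    cost_elective_coiling = scalar("cost_elective_coiling",
                                   function(p) pct25(p$cost_elective_coiling)),
    cost_elective_clipping = scalar("cost_elective_clipping",
                                    function(p) pct25(p$cost_elective_clipping)),
    cost_emergency_coiling = scalar("cost_emergency_coiling",
                                    function(p) pct25(p$cost_emergency_coiling)),
    cost_emergency_clipping = scalar("cost_emergency_clipping",
                                     function(p) pct25(p$cost_emergency_clipping)),
    cost_nursing_unfavorable_annual =
      scalar("cost_nursing_unfavorable_annual",
             function(p) pct25(p$cost_nursing_unfavorable_annual)),
    coiling_fraction = scalar("coiling_fraction", function(p) c(0, 1)),
    utility_favorable = scalar("utility_favorable", function(p) c(0.60, 1.00)),
    utility_unfavorable = scalar("utility_unfavorable", function(p) c(0.11, 0.71)),
    utility_no_rebleed = scalar("utility_no_rebleed", function(p) c(0.41, 0.72))
  )
}

#' Names of parameters registered for one-way sensitivity analysis
#'
#' Scalar fields are swept directly. Components of outcome simplexes are
#' registered individually: sweeping one rescales its siblings so the vector
#' stays on the simplex, except for the no-aneurysm outcome whose
#' favorable/unfavorable values are independent with death as the remainder.
#'
#' @return Character vector of registered parameter names.
#' @export
registered_parameters <- function() names(param_registry())

lookup_param <- function(name) {
  reg <- param_registry()
  if (!name %in% names(reg)) {
    stop("unknown parameter '", name, "'; registered parameters: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[name]]
}

#' Default one-way range of a registered parameter
#'
#' Published ranges where they exist (age 50-80, prevalence 5-35%, CTA
#' sensitivity 20-99% and specificity 20-100%, the utility ranges, the
#' no-aneurysm outcome ranges), otherwise +/-25% of the base value.
#'
#' @param name Registered parameter name.
#' @param p A `parameter_set`.
#' @return Numeric `c(low, high)`.
#' @export
default_range <- function(name, p = default_parameters()) {
  lookup_param(name)$range(p)
}

evaluate_at <- function(name, x, p, tm, wtp = 20000) {
  entry <- lookup_param(name)
  p2 <- entry$set(p, x)
  ref <- evaluate_strategy("no_repeat", p2, tm)
  comp <- evaluate_strategy("repeat_cta", p2, tm)
  incremental_analysis(ref, comp, wtp = wtp)
}

#' One-way deterministic sensitivity sweep
#'
#' Evaluates both strategies over a grid of values of a single registered
#' parameter, all other parameters held at base case.
#'
#' @param param Registered parameter name (see [registered_parameters()]).
#' @param low,high Sweep bounds (`low <= high`; equal bounds give a
#'   degenerate one-point grid).
#' @param n_points Number of grid points (>= 2 unless the range is
#'   degenerate).
#' @param p A `parameter_set`.
#' @param tm A `transition_model`.
#' @param wtp Willingness-to-pay used for the per-point net monetary benefit.
#' @return A `sweep_result` data frame: one row per grid value with both
#'   strategies' costs and QALYs, the incremental quantities, the ICER
#'   (`NA` under dominance/equality) and the dominance label.
#' @export
one_way <- function(param, low = NULL, high = NULL, n_points = 11,
                    p = default_parameters(), tm = default_transition_model(),
                    wtp = 20000) {
  rng <- default_range(param, p)
  if (is.null(low)) low <- rng[1]
  if (is.null(high)) high <- rng[2]
  if (low > high) stop("low must not exceed high", call. = FALSE)
  grid <- if (low == high) low else seq(low, high, length.out = max(2L, n_points))
  rows <- lapply(grid, function(x) {
    cmp <- evaluate_at(param, x, p, tm, wtp)
    data.frame(
      parameter = param, value = x,
      cost_no_repeat = cmp$reference$expected_cost,
      qaly_no_repeat = cmp$reference$expected_qaly,
      cost_repeat_cta = cmp$comparator$expected_cost,
      qaly_repeat_cta = cmp$comparator$expected_qaly,
      delta_cost = cmp$delta_cost, delta_qaly = cmp$delta_qaly,
      icer = if (cmp$label == "icer") cmp$icer else NA_real_,
      label = cmp$label, nmb = cmp$nmb,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

# Signed distance of the comparator from cost-effectiveness at wtp:
# negative = cost-effective. Dominance maps to signed infinities so the
# bisection in threshold_search always has a sign to work with.
icer_gap <- function(cmp, wtp) {
  switch(cmp$label,
    dominant = -Inf,
    dominated = Inf,
    undefined = if (cmp$delta_cost > 0) Inf else -Inf,
    icer = if (cmp$delta_qaly > 0) {
      cmp$icer - wtp
    } else {
      # less effective and cheaper: cost-effective only if savings per QALY
      # forgone exceed wtp, i.e. icer > wtp; flip the sign accordingly
      wtp - cmp$icer
    }
  )
}

#' Tornado analysis over a set of parameters
#'
#' Evaluates the ICER at both ends of each parameter's range and orders the
#' bars by descending span.
#'
#' @param params Character vector of registered parameter names, or a named
#'   list mapping names to `c(low, high)` ranges; `NULL` range entries (and
#'   plain names) use [default_range()].
#' @param p A `parameter_set`.
#' @param tm A `transition_model`.
#' @param wtp Willingness-to-pay used for dominance-aware ordering.
#' @return A `tornado_result` data frame sorted by descending `span`, with
#'   the parameter, its low/high values, the ICER and dominance label at each
#'   end.
#' @export
tornado <- function(params = registered_parameters(),
                    p = default_parameters(), tm = default_transition_model(),
                    wtp = 20000) {
  if (!length(params)) stop("at least one parameter required", call. = FALSE)
  if (!is.list(params)) {
    params <- stats::setNames(vector("list", length(params)), params)
  }
  rows <- lapply(names(params), function(nm) {
    rng <- params[[nm]]
    if (is.null(rng)) rng <- default_range(nm, p)
    lo <- evaluate_at(nm, rng[1], p, tm, wtp)
    hi <- evaluate_at(nm, rng[2], p, tm, wtp)
    icer_of <- function(cmp) if (cmp$label == "icer") cmp$icer else NA_real_
    # span on the wtp-gap scale so dominance at an endpoint still ranks;
    # infinities are clamped to keep the ordering finite and stable
    gap <- function(cmp) max(min(icer_gap(cmp, wtp), 1e12), -1e12)
    data.frame(
      parameter = nm, low = rng[1], high = rng[2],
      icer_low = icer_of(lo), icer_high = icer_of(hi),
      label_low = lo$label, label_high = hi$label,
      span = abs(gap(hi) - gap(lo)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tornado_result", "data.frame")
  out
}

#' Willingness-to-pay threshold search over one parameter
#'
#' Finds the parameter value at which the comparator's ICER crosses a
#' willingness-to-pay threshold, by bisection on the signed gap
#' `ICER(x) - wtp` (dominant and dominated configurations mapped to -Inf and
#' +Inf respectively). A coarse scan of the bracket first locates sign
#' changes; if several exist the crossing nearest the base-case value is
#' returned and flagged.
#'
#' @param param Registered parameter name.
#' @param wtp Willingness-to-pay threshold (GBP/QALY).
#' @param bracket `c(lo, hi)` search interval within the parameter's valid
#'   domain; default is the parameter's registered range.
#' @param p A `parameter_set`.
#' @param tm A `transition_model`.
#' @param tol Relative bracket-width tolerance for the bisection.
#' @param scan_points Coarse-scan resolution used to locate sign changes.
#' @return A `threshold_result` list: `crossing` (numeric, or `NA` with
#'   `status = "no crossing"`), `status`, `direction`
#'   (`"cost_effective_below"` / `"cost_effective_above"`), `multiple`
#'   (TRUE when several sign changes were found), `n_evaluations`, and the
#'   searched `bracket`.
#' @export
threshold_search <- function(param, wtp = 20000, bracket = NULL,
                             p = default_parameters(),
                             tm = default_transition_model(),
                             tol = 1e-4, scan_points = 41) {
  if (is.null(bracket)) bracket <- default_range(param, p)
  lo <- bracket[1]; hi <- bracket[2]
  if (lo >= hi) stop("bracket must satisfy lo < hi", call. = FALSE)
  n_eval <- 0L
  f <- function(x) {
    n_eval <<- n_eval + 1L
    icer_gap(evaluate_at(param, x, p, tm, wtp), wtp)
  }
  grid <- seq(lo, hi, length.out = scan_points)
  fg <- vapply(grid, f, numeric(1))
  sgn <- sign(fg)
  # treat exact zeros as crossings at the grid point
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  zeros <- grid[sgn == 0]
  result <- function(crossing, status, multiple) {
    direction <- if (fg[1] < 0) "cost_effective_below" else "cost_effective_above"
    structure(
      list(parameter = param, wtp = wtp, crossing = crossing, status = status,
           direction = direction, multiple = multiple,
           n_evaluations = n_eval, bracket = c(lo, hi)),
      class = "threshold_result"
    )
  }
  if (!length(flips) && !length(zeros)) {
    return(result(NA_real_, "no crossing", FALSE))
  }
  bisect <- function(a, b) {
    fa <- f(a)
    width0 <- b - a
    while ((b - a) > tol * width0) {
      m <- (a + b) / 2
      fm <- f(m)
      if (fm == 0) return(m)
      if (sign(fm) == sign(fa)) { a <- m; fa <- fm } else { b <- m }
    }
    (a + b) / 2
  }
  crossings <- c(zeros, vapply(flips, function(i) bisect(grid[i], grid[i + 1]),
                               numeric(1)))
  base_value <- lookup_param(param)$get(p)
  crossing <- crossings[which.min(abs(crossings - base_value))]
  result(crossing, "crossing", length(crossings) > 1L)
}

#' Write a sweep or tornado result to CSV
#'
#' @param x A `sweep_result` or `tornado_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> %s at WTP £%s: ", x$parameter,
              format(x$wtp, big.mark = ",")))
  if (x$status == "no crossing") {
    cat("no crossing in [", x$bracket[1], ", ", x$bracket[2], "]\n", sep = "")
  } else {
    cat(sprintf("crossing at %.6g (%s)%s\n", x$crossing,
                gsub("_", " ", x$direction),
                if (x$multiple) " [multiple sign changes; nearest to base returned]" else ""))
  }
  invisible(x)
}
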