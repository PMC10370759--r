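# Report-level rounding conventions: money to 2 decimals, QALYs to 3,
# probabilities to 4.
fmt_money <- function(x) formatC(x, format = "f", digits = 2, big.mark = ",")
fmt_qaly <- function(x) formatC(x, format = "f", digits = 3)
fmt_prob <- function(x) formatC(x, format = "f", digits = 4)

log_msg <- function(...) message(sprintf(...)) # message() writes to stderr

build_model_inputs <- function(config = NULL, life_table = NULL,
                               rebleed_schedule = NULL, transitions = NULL) {
  p <- load_parameters(config)
  lt <- if (is.null(life_table)) gompertz_life_table() else read_life_table(life_table)
  rs <- if (is.null(rebleed_schedule)) default_rebleed_schedule() else
    read_rebleed_schedule(rebleed_schedule)
  mx <- if (is.null(transitions)) NULL else read_transition_matrix(transitions)
  list(p = p, tm = transition_model(lt, rs, mx))
}

#' Run manifest for an analysis invocation
#'
#' Records what produced an output set: the command, configuration path,
#' seed, input-file MD5 digests, package version and timestamp. Digests are
#' stable for identical inputs, so two runs of the same command on the same
#' inputs are provably comparing like with like.
#'
#' @param command Command label.
#' @param config Configuration path or `NULL`.
#' @param seed Seed used, or `NA`.
#' @param files Character vector of input file paths to digest.
#' @return A list suitable for JSON serialization.
#' @export
run_manifest <- function(command, config = NULL, seed = NA, files = character(0)) {
  files <- files[!vapply(files, is.null, logical(1))]
  digests <- if (length(files)) as.list(tools::md5sum(unlist(files))) else list()
  list(
    command = command,
    config = if (is.null(config)) "packaged defaults" else config,
    seed = seed,
    input_digests = digests,
    package_version = as.character(utils::packageVersion("sahcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

comparison_to_list <- function(cmp, wtps) {
  list(
    strategies = list(
      no_repeat = list(cost = cmp$reference$expected_cost,
                       qaly = cmp$reference$expected_qaly),
      repeat_cta = list(cost = cmp$comparator$expected_cost,
                        qaly = cmp$comparator$expected_qaly)
    ),
    delta_cost = cmp$delta_cost,
    delta_qaly = cmp$delta_qaly,
    icer = if (cmp$label == "icer") cmp$icer else NULL,
    label = cmp$label,
    nmb = lapply(stats::setNames(wtps, paste0("wtp_", wtps)),
                 function(w) w * cmp$delta_qaly - cmp$delta_cost)
  )
}

#' Base-case cost-effectiveness report
#'
#' Evaluates both strategies at base case and prints a two-row
#' cost/effectiveness table with the incremental comparison and the net
#' monetary benefit at the requested thresholds.
#'
#' @param config Optional YAML configuration path (packaged defaults when
#'   `NULL`).
#' @param life_table,rebleed_schedule,transitions Optional CSV overrides for
#'   the packaged fixtures.
#' @param wtp Willingness-to-pay thresholds reported (GBP/QALY).
#' @param json If `TRUE`, print a machine-readable JSON comparison instead
#'   of the table.
#' @param out_dir Optional directory for `base_case.json` and a run
#'   manifest.
#' @return The `ce_comparison`, invisibly.
#' @export
cmd_base_case <- function(config = NULL, life_table = NULL,
                          rebleed_schedule = NULL, transitions = NULL,
                          wtp = c(20000, 30000), json = FALSE, out_dir = NULL) {
  inp <- build_model_inputs(config, life_table, rebleed_schedule, transitions)
  ref <- evaluate_strategy("no_repeat", inp$p, inp$tm)
  comp <- evaluate_strategy("repeat_cta", inp$p, inp$tm)
  cmp <- incremental_analysis(ref, comp, wtp = wtp[1])
  payload <- comparison_to_list(cmp, wtp)
  if (json) {
    cat(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE), "\n")
  } else {
    cat(sprintf("%-32s %14s %12s %14s %10s %12s\n", "Strategy", "Cost (£)",
                "QALYs", "Incr. cost", "Incr. Q", "ICER (£/QALY)"))
    cat(sprintf("%-32s %14s %12s %14s %10s %12s\n", "No repeat delayed imaging",
                fmt_money(ref$expected_cost), fmt_qaly(ref$expected_qaly),
                "-", "-", "-"))
    icer_txt <- if (cmp$label == "icer") fmt_money(cmp$icer) else cmp$label
    cat(sprintf("%-32s %14s %12s %14s %10s %12s\n", "Repeat delayed imaging (CTA)",
                fmt_money(comp$expected_cost), fmt_qaly(comp$expected_qaly),
                fmt_money(cmp$delta_cost), fmt_qaly(cmp$delta_qaly), icer_txt))
    for (w in wtp) {
      cat(sprintf("NMB at £%s/QALY: £%s\n", format(w, big.mark = ","),
                  fmt_money(w * cmp$delta_qaly - cmp$delta_cost)))
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(payload, file.path(out_dir, "base_case.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(
      run_manifest("base-case", config,
                   files = c(config, life_table, rebleed_schedule, transitions)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(cmp)
}

#' One-way sensitivity analysis report
#'
#' Sweeps each requested parameter over its range, writes one sweep CSV per
#' parameter plus an ordered tornado CSV (with the willingness-to-pay
#' crossing where one exists inside the range), and returns the tornado.
#'
#' @inheritParams cmd_base_case
#' @param params Parameter names, or `"all"` for every registered parameter.
#' @param wtp Willingness-to-pay threshold for crossings (GBP/QALY).
#' @param n_points Grid resolution of each sweep.
#' @return The `tornado_result` (with a `threshold` column), invisibly.
#' @export
cmd_dsa <- function(config = NULL, params = "all", life_table = NULL,
                    rebleed_schedule = NULL, transitions = NULL,
                    wtp = 20000, n_points = 11, out_dir = NULL) {
  inp <- build_model_inputs(config, life_table, rebleed_schedule, transitions)
  if (identical(params, "all")) params <- registered_parameters()
  unknown <- setdiff(params, registered_parameters())
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         "; registered: ", paste(registered_parameters(), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in params) {
    sw <- one_way(nm, n_points = n_points, p = inp$p, tm = inp$tm, wtp = wtp)
    if (!is.null(out_dir)) {
      write_sensitivity_csv(sw, file.path(out_dir, paste0("sweep_", nm, ".csv")))
    }
  }
  tor <- tornado(params, p = inp$p, tm = inp$tm, wtp = wtp)
  tor$threshold <- vapply(tor$parameter, function(nm) {
    ts <- threshold_search(nm, wtp = wtp, p = inp$p, tm = inp$tm)
    ts$crossing
  }, numeric(1))
  if (!is.null(out_dir)) {
    write_sensitivity_csv(tor, file.path(out_dir, "tornado.csv"))
    jsonlite::write_json(
      run_manifest("dsa", config,
                   files = c(config, life_table, rebleed_schedule, transitions)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  log_msg("tornado: %d bars, widest = %s", nrow(tor), tor$parameter[1])
  invisible(tor)
}

#' Probabilistic sensitivity analysis report
#'
#' Runs the PSA, writes the per-iteration scatter CSV, the CEAC CSV, a
#' summary JSON (including the probability the repeat strategy is
#' cost-effective at the primary threshold) and a run manifest.
#'
#' @inheritParams cmd_base_case
#' @param n Monte Carlo iterations (default 5000).
#' @param seed RNG seed.
#' @param wtp Primary willingness-to-pay threshold for the summary.
#' @param wtp_grid CEAC grid.
#' @return The `psa_summary` list, invisibly.
#' @export
cmd_psa <- function(config = NULL, n = 5000, seed = 1,
                    life_table = NULL, rebleed_schedule = NULL,
                    transitions = NULL, wtp = 20000,
                    wtp_grid = seq(0, 50000, by = 1000), out_dir = NULL) {
  inp <- build_model_inputs(config, life_table, rebleed_schedule, transitions)
  r <- run_psa(inp$p, inp$tm, n = n, seed = seed)
  curve <- ceac(r, wtp_grid)
  s <- psa_summary(r, wtp = wtp)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(r$draws, file.path(out_dir, "psa_scatter.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(curve), file.path(out_dir, "ceac.csv"),
                     row.names = FALSE)
    jsonlite::write_json(s, file.path(out_dir, "psa_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(
      run_manifest("psa", config, seed = seed,
                   files = c(config, life_table, rebleed_schedule, transitions)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  cat(sprintf("P(repeat CTA cost-effective at £%s/QALY) = %s  (n = %d, seed = %d)\n",
              format(wtp, big.mark = ","), fmt_prob(s$p_repeat_cost_effective),
              n, seed))
  invisible(s)
}

#' Willingness-to-pay threshold report for one parameter
#'
#' @inheritParams cmd_base_case
#' @param param Registered parameter name.
#' @param wtp Willingness-to-pay threshold (GBP/QALY).
#' @param bracket Optional `c(lo, hi)` search interval.
#' @return The `threshold_result`, invisibly.
#' @export
cmd_threshold <- function(config = NULL, param, wtp = 20000, bracket = NULL,
                          life_table = NULL, rebleed_schedule = NULL,
                          transitions = NULL, out_dir = NULL) {
  inp <- build_model_inputs(config, life_table, rebleed_schedule, transitions)
  ts <- threshold_search(param, wtp = wtp, bracket = bracket,
                         p = inp$p, tm = inp$tm)
  log_msg("threshold_search(%s): %d model evaluations over [%g, %g]",
          param, ts$n_evaluations, ts$bracket[1], ts$bracket[2])
  print(ts)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      ts[c("parameter", "wtp", "crossing", "status", "direction", "multiple")],
      file.path(out_dir, paste0("threshold_", param, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(ts)
}
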