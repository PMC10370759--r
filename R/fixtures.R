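#' Synthetic Gompertz background-mortality life table
#'
#' Builds an age-indexed table of annual all-cause death probabilities from a
#' Gompertz law, `qx(age) = min(1, a * exp(b * age))`, closed at `cap` where
#' `qx` is forced to 1. The defaults give an adult-mortality shape of the
#' right order for a high-income population; this is a synthetic stand-in,
#' not a national life table, and replication against a real table is done by
#' supplying one via [read_life_table()].
#'
#' @param a Baseline annual death rate at age 0 (probability scale).
#' @param b Log-increase in mortality per year of age.
#' @param cap Closing age (qx forced to 1 there).
#' @return A data frame with columns `age` (0..cap) and `qx`.
#' @examples
#' lt <- gompertz_life_table()
#' lt$qx[lt$age == 55]
#' @export
gompertz_life_table <- function(a = 2.3e-5, b = 0.095, cap = 100) {
  stopifnot(a > 0, b >= 0, cap > 0)
  age <- 0:cap
  qx <- pmin(1, a * exp(b * age))
  qx[length(qx)] <- 1
  data.frame(age = age, qx = qx)
}

check_life_table <- function(lt) {
  if (!is.data.frame(lt) || !all(c("age", "qx") %in% names(lt))) {
    stop("life table needs columns age, qx", call. = FALSE)
  }
  if (any(lt$qx < 0 | lt$qx > 1)) stop("life table qx outside [0, 1]", call. = FALSE)
  if (any(diff(lt$age) != 1)) stop("life table ages must be contiguous", call. = FALSE)
  if (lt$qx[nrow(lt)] != 1) stop("life table must close with qx = 1", call. = FALSE)
  invisible(lt)
}

#' Synthetic annual re-bleed probability schedule
#'
#' Annual probability of aneurysm re-rupture by year since presentation for
#' patients harboring an occult (untreated) aneurysm. The packaged default is
#' a synthetic placeholder with the natural-history shape reported for
#' conservatively managed ruptured aneurysms — a high residual first-year
#' risk for patients who have already survived the first week, declining to
#' roughly 3% per year long term — not the cohort values the published
#' analysis drew from its supplement; supply those via
#' [read_rebleed_schedule()] for replication.
#'
#' @param tail `"constant"` extends the last listed probability to all later
#'   years; `"zero"` assumes no re-bleed risk beyond the listed years.
#' @return A data frame with columns `year` (1..10) and `prob`, carrying a
#'   `tail` attribute.
#' @export
default_rebleed_schedule <- function(tail = c("constant", "zero")) {
  tail <- match.arg(tail)
  sched <- data.frame(
    year = 1:10,
    prob = c(0.35, 0.10, 0.05, 0.04, 0.03, 0.03, 0.03, 0.03, 0.03, 0.03)
  )
  attr(sched, "tail") <- tail
  sched
}

check_rebleed_schedule <- function(s) {
  if (!is.data.frame(s) || !all(c("year", "prob") %in% names(s))) {
    stop("re-bleed schedule needs columns year, prob", call. = FALSE)
  }
  if (any(s$year < 1 | s$year != round(s$year))) {
    stop("schedule years must be integers >= 1", call. = FALSE)
  }
  if (any(s$prob < 0 | s$prob > 1)) {
    stop("schedule probabilities outside [0, 1]", call. = FALSE)
  }
  invisible(s)
}

check_transition_matrix <- function(m) {
  if (!is.data.frame(m) || !all(c("from", "to", "prob") %in% names(m))) {
    stop("transition matrix needs columns from, to, prob", call. = FALSE)
  }
  allowed <- c("favorable", "unfavorable", "dead")
  if (!all(m$from %in% c("favorable", "unfavorable")) || !all(m$to %in% allowed)) {
    stop("transition matrix states must be favorable/unfavorable/dead", call. = FALSE)
  }
  if (any(m$prob < 0 | m$prob > 1)) {
    stop("transition probabilities outside [0, 1]", call. = FALSE)
  }
  for (fr in unique(m$from)) {
    s <- sum(m$prob[m$from == fr])
    if (abs(s - 1) > 1e-9) {
      stop(sprintf("transition row '%s' sums to %.10f, not 1", fr, s), call. = FALSE)
    }
  }
  invisible(m)
}

skip_comments <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a life table CSV
#'
#' Expects headered columns `age,qx`; lines starting `#` are comments.
#' @param path CSV path.
#' @return A validated life-table data frame.
#' @export
read_life_table <- function(path) {
  lt <- skip_comments(path)
  check_life_table(lt)
}

#' Read a re-bleed schedule CSV
#'
#' Expects headered columns `year,prob`; lines starting `#` are comments.
#' @param path CSV path.
#' @param tail Tail rule beyond the listed years (`"constant"` or `"zero"`).
#' @return A validated schedule data frame with the `tail` attribute set.
#' @export
read_rebleed_schedule <- function(path, tail = c("constant", "zero")) {
  tail <- match.arg(tail)
  s <- skip_comments(path)
  attr(s, "tail") <- tail
  check_rebleed_schedule(s)
}

#' Read an annual transition matrix CSV
#'
#' Expects headered columns `from,to,prob` over the favorable/unfavorable
#' living states (destination may also be `dead`); each `from` row must sum
#' to 1. Used to override the default per-state mortality rule with a full
#' post-treatment transition matrix.
#'
#' @param path CSV path.
#' @return A validated transition-matrix data frame.
#' @export
read_transition_matrix <- function(path) {
  check_transition_matrix(skip_comments(path))
}

#' Default transition model
#'
#' Assembles a [transition_model()] from the packaged synthetic fixtures: the
#' Gompertz life table and the placeholder re-bleed schedule, in
#' state-mortality mode (annual favorable/unfavorable death probabilities
#' read from the parameter set, no crossover). Pass a matrix to switch to
#' full-matrix mode.
#'
#' @inheritParams transition_model
#' @return A `transition_model`.
#' @export
default_transition_model <- function(life_table = gompertz_life_table(),
                                     rebleed_schedule = default_rebleed_schedule(),
                                     matrix = NULL) {
  transition_model(life_table, rebleed_schedule, matrix)
}

#' Write the packaged fixture files
#'
#' Emits `defaults.yaml` (the full default parameter set), `life_table.csv`,
#' `rebleed_schedule.csv` and `transitions.csv` into a directory. Each CSV
#' carries a `# source: fixture` header marking it as a synthetic stand-in.
#' Writing is idempotent: running twice produces identical bytes.
#'
#' @param directory Output directory (created if absent).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_fixture_files <- function(directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory, call. = FALSE)
  }
  p <- default_parameters()
  paths <- c(
    defaults = file.path(directory, "defaults.yaml"),
    life_table = file.path(directory, "life_table.csv"),
    rebleed_schedule = file.path(directory, "rebleed_schedule.csv"),
    transitions = file.path(directory, "transitions.csv")
  )
  write_parameters(p, paths[["defaults"]])

  write_fixture_csv <- function(df, path, note) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# source: fixture", paste0("# ", note)), con)
    utils::write.csv(df, con, row.names = FALSE)
  }
  write_fixture_csv(
    gompertz_life_table(), paths[["life_table"]],
    "synthetic Gompertz background mortality, qx = min(1, 2.3e-5 * exp(0.095 * age))"
  )
  write_fixture_csv(
    default_rebleed_schedule(), paths[["rebleed_schedule"]],
    "synthetic annual re-bleed probabilities by year since presentation; constant tail"
  )
  sm <- p$state_mortality
  trans <- data.frame(
    from = c("favorable", "favorable", "unfavorable", "unfavorable"),
    to = c("favorable", "dead", "unfavorable", "dead"),
    prob = c(1 - sm[["favorable"]], sm[["favorable"]],
             1 - sm[["unfavorable"]], sm[["unfavorable"]])
  )
  write_fixture_csv(
    trans, paths[["transitions"]],
    "annual post-event transition rows equivalent to the default state-mortality rule"
  )
  invisible(paths)
}
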