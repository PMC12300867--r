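#' Run one scenario across all strata
#'
#' Composes the risk model, the Markov cohort engine and the cost accrual for
#' every stratum of a parameter set under one intake scenario. The incidence
#' multiplier fed to the engine is the zero-intake-referenced dose-response
#' factor `rr^(achieved intake / increment)` (see [scenario_rr_table()] with
#' `reference = "zero"`): the published incidence rates are attenuated by the
#' scenario's achieved intake in every arm, baseline included, which is the
#' calibration that reproduces the published projections; the reference
#' cancels in all baseline-versus-scenario comparisons.
#'
#' @param ps A [parameter_set()].
#' @param sc A [scenario()].
#' @param cost_timing Cost accrual timing, see [cumulative_discounted_nhe()].
#' @param rr_bound Dose-response value to use (point estimate or a CI bound),
#'   see [rr_for_intake_change()].
#' @return A `scenario_result`: data.frame with one row per stratum
#'   (`sex`, `age_band`, `population`, `cum_incidence`, `cum_t2d_deaths`,
#'   `cum_discounted_nhe_usd`) and attributes `scenario` (name) and
#'   `horizon`.
#' @export
#' @examples
#' base <- run_scenario(japan_2019(), baseline_scenario())
#' sum(base$cum_incidence)  # ~2.22 million new cases over 10 years
run_scenario <- function(ps, sc, cost_timing = c("end", "start"),
                         rr_bound = c("point", "ci_low", "ci_high")) {
  stopifnot(inherits(ps, "parameter_set"), inherits(sc, "scenario"))
  cost_timing <- match.arg(cost_timing)
  rr_bound <- match.arg(rr_bound)
  rr_tab <- scenario_rr_table(ps, sc, reference = "zero", bound = rr_bound)
  n <- nrow(ps$strata)
  out <- data.frame(
    sex = ps$strata$sex, age_band = ps$strata$age_band,
    population = ps$strata$population,
    cum_incidence = numeric(n), cum_t2d_deaths = numeric(n),
    cum_discounted_nhe_usd = numeric(n)
  )
  cost_key <- stratum_key(ps$costs)
  for (i in seq_len(n)) {
    stratum <- ps$strata[i, ]
    trace <- run_cohort(stratum, rr_tab$rr_multiplier[i], ps$horizon)
    cost_row <- match(stratum_key(stratum), cost_key)
    cpp <- per_patient_annual_cost(
      ps$costs$annual_outpatient_nhe_usd[cost_row], stratum)
    out$cum_incidence[i] <- cumulative_incidence(trace)
    out$cum_t2d_deaths[i] <- cumulative_t2d_deaths(trace)
    out$cum_discounted_nhe_usd[i] <- cumulative_discounted_nhe(
      trace, cpp, ps$discount_rate, timing = cost_timing)
  }
  structure(out, scenario = sc$name, horizon = ps$horizon,
            class = c("scenario_result", "data.frame"))
}

#' Aggregate a scenario result by sex and overall
#'
#' @param result A `scenario_result` (or the comparison table from
#'   [compare_scenarios()]).
#' @param cols Numeric columns to sum; defaults to all numeric columns.
#' @return data.frame with one row per sex plus an `"all"` row; sums over
#'   strata.
#' @export
aggregate_result <- function(result, cols = NULL) {
  if (is.null(cols)) {
    cols <- names(result)[vapply(result, is.numeric, logical(1))]
  }
  groups <- c(split(seq_len(nrow(result)), result$sex),
              list(all = seq_len(nrow(result))))
  rows <- lapply(names(groups), function(g) {
    sums <- lapply(result[groups[[g]], cols, drop = FALSE], sum)
    cbind(data.frame(group = g), as.data.frame(sums))
  })
  do.call(rbind, rows)
}

#' Compare a scenario with the baseline
#'
#' Per-stratum and aggregated prevention effects: prevented T2D cases,
#' prevented T2D deaths and saved discounted expenditure, each absolute
#' (`baseline - scenario`) and as percent of baseline. Percentages are
#' computed from unrounded values; aggregates are summed before
#' percentage-taking.
#'
#' @param baseline,scenario Two `scenario_result`s over the same strata and
#'   horizon.
#' @return A `comparison_result`: list with `by_stratum` and `aggregated`
#'   data frames, each carrying `prevented_incidence`, `prevented_deaths`,
#'   `saved_nhe_usd` and the corresponding `*_pct` columns, plus attribute
#'   `scenario`.
#' @export
#' @examples
#' ps <- japan_2019()
#' cmp <- compare_scenarios(run_scenario(ps, baseline_scenario()),
#'                          run_scenario(ps, scenario("scenario1", 160)))
#' cmp$aggregated
compare_scenarios <- function(baseline, scenario) {
  stopifnot(inherits(baseline, "scenario_result"),
            inherits(scenario, "scenario_result"))
  if (!identical(stratum_key(baseline), stratum_key(scenario))) {
    stop("compare_scenarios: results cover different strata")
  }
  if (!identical(attr(baseline, "horizon"), attr(scenario, "horizon"))) {
    stop("compare_scenarios: results have different horizons")
  }
  diff_tab <- data.frame(
    sex = baseline$sex, age_band = baseline$age_band,
    baseline_incidence = baseline$cum_incidence,
    baseline_deaths = baseline$cum_t2d_deaths,
    baseline_nhe_usd = baseline$cum_discounted_nhe_usd,
    prevented_incidence = baseline$cum_incidence - scenario$cum_incidence,
    prevented_deaths = baseline$cum_t2d_deaths - scenario$cum_t2d_deaths,
    saved_nhe_usd = baseline$cum_discounted_nhe_usd -
      scenario$cum_discounted_nhe_usd
  )
  pct <- function(part, whole) ifelse(whole > 0, 100 * part / whole, NA_real_)
  add_pct <- function(tab) {
    tab$prevented_incidence_pct <- pct(tab$prevented_incidence,
                                       tab$baseline_incidence)
    tab$prevented_deaths_pct <- pct(tab$prevented_deaths, tab$baseline_deaths)
    tab$saved_nhe_pct <- pct(tab$saved_nhe_usd, tab$baseline_nhe_usd)
    tab
  }
  agg <- aggregate_result(
    diff_tab,
    cols = c("baseline_incidence", "baseline_deaths", "baseline_nhe_usd",
             "prevented_incidence", "prevented_deaths", "saved_nhe_usd"))
  structure(
    list(by_stratum = add_pct(diff_tab), aggregated = add_pct(agg)),
    scenario = attr(scenario, "scenario"),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  a <- x$aggregated[x$aggregated$group == "all", ]
  cat(sprintf(
    "<comparison_result> scenario '%s' vs baseline\n  prevented T2D cases: %.0f (%.1f%%)\n  prevented T2D deaths: %.0f (%.1f%%)\n  saved discounted NHE: %.0f USD (%.1f%%)\n",
    attr(x, "scenario"),
    a$prevented_incidence, a$prevented_incidence_pct,
    a$prevented_deaths, a$prevented_deaths_pct,
    a$saved_nhe_usd, a$saved_nhe_pct))
  invisible(x)
}

format_report_block <- function(by_stratum, aggregated, cols) {
  sexes <- unique(by_stratum$sex)
  rows <- lapply(sexes, function(sx) {
    agg_row <- aggregated[aggregated$group == sx, , drop = FALSE]
    head_row <- cbind(data.frame(sex = sx, age_band = "total"),
                      agg_row[, cols, drop = FALSE])
    strata_rows <- by_stratum[by_stratum$sex == sx,
                              c("sex", "age_band", cols), drop = FALSE]
    rbind(head_row, strata_rows)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write report tables for a set of results
#'
#' Writes CSV tables mirroring the published presentation: a baseline
#' projection table (per-stratum rows with per-sex totals) and, for each
#' comparison, a prevention table and a savings table, plus a short
#' human-readable `summary.txt`. CSV values are unrounded; only the summary
#' rounds for display.
#'
#' @param dir Output directory, created if absent.
#' @param baseline A `scenario_result` for the baseline.
#' @param comparisons List of `comparison_result`s (may be empty only if
#'   `baseline` is given alone; an empty `baseline` is an error).
#' @return Invisibly, the character vector of files written.
#' @export
render_report <- function(dir, baseline, comparisons = list()) {
  stopifnot(inherits(baseline, "scenario_result"))
  if (nrow(baseline) == 0) stop("render_report: empty baseline result")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()

  base_cols <- c("population", "cum_incidence", "cum_t2d_deaths",
                 "cum_discounted_nhe_usd")
  base_tab <- format_report_block(
    baseline, aggregate_result(baseline, cols = base_cols), base_cols)
  f <- file.path(dir, "baseline_projection.csv")
  utils::write.csv(base_tab, f, row.names = FALSE)
  files <- c(files, f)

  summary_lines <- c(
    sprintf("Baseline (%d-year horizon): %.0f new T2D cases, %.0f T2D deaths, %.0f USD discounted NHE",
            attr(baseline, "horizon"), sum(baseline$cum_incidence),
            sum(baseline$cum_t2d_deaths),
            sum(baseline$cum_discounted_nhe_usd)))

  for (cmp in comparisons) {
    stopifnot(inherits(cmp, "comparison_result"))
    name <- attr(cmp, "scenario")
    prev_cols <- c("prevented_incidence", "prevented_incidence_pct",
                   "prevented_deaths", "prevented_deaths_pct")
    save_cols <- c("saved_nhe_usd", "saved_nhe_pct")
    f1 <- file.path(dir, paste0("prevention_", name, ".csv"))
    utils::write.csv(
      format_report_block(cmp$by_stratum, cmp$aggregated, prev_cols),
      f1, row.names = FALSE)
    f2 <- file.path(dir, paste0("savings_", name, ".csv"))
    utils::write.csv(
      format_report_block(cmp$by_stratum, cmp$aggregated, save_cols),
      f2, row.names = FALSE)
    files <- c(files, f1, f2)
    a <- cmp$aggregated[cmp$aggregated$group == "all", ]
    summary_lines <- c(summary_lines, sprintf(
      "%s vs baseline: %.0f cases prevented (%.1f%%), %.0f T2D deaths prevented (%.1f%%), %.0f USD saved (%.1f%%)",
      name, a$prevented_incidence, a$prevented_incidence_pct,
      a$prevented_deaths, a$prevented_deaths_pct,
      a$saved_nhe_usd, a$saved_nhe_pct))
  }

  f <- file.path(dir, "summary.txt")
  writeLines(summary_lines, f)
  files <- c(files, f)
  invisible(files)
}
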