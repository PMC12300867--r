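SENSITIVITY_PARAMETERS <- c("incidence", "prevalence", "t2d_mortality",
                            "all_cause_mortality", "relative_risk",
                            "discount_rate")

perturb_parameter_set <- function(ps, parameter, bound) {
  cols <- switch(parameter,
    incidence = c("incidence_per100k", "incidence_lo", "incidence_hi"),
    prevalence = c("prevalence_per100k", "prevalence_lo", "prevalence_hi"),
    t2d_mortality = c("t2d_mort_per100k", "t2d_mort_lo", "t2d_mort_hi"),
    all_cause_mortality = c("allcause_mort_per100k", "allcause_mort_lo",
                            "allcause_mort_hi"),
    NULL
  )
  if (!is.null(cols)) {
    src <- if (bound == "lower") cols[2] else cols[3]
    ps$strata[[cols[1]]] <- ps$strata[[src]]
  }
  ps
}

savings_by_group <- function(ps, sc, cost_timing, rr_bound = "point") {
  base <- run_scenario(ps, baseline_scenario(), cost_timing = cost_timing,
                       rr_bound = rr_bound)
  scen <- run_scenario(ps, sc, cost_timing = cost_timing,
                       rr_bound = rr_bound)
  cmp <- compare_scenarios(base, scen)
  agg <- cmp$aggregated
  stats::setNames(agg$saved_nhe_usd, agg$group)
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the full pipeline (baseline and scenario, both arms perturbed
#' identically) with one parameter moved to its lower and then its upper
#' uncertainty bound, all other parameters held at their point values, and
#' reports the resulting cumulative discounted NHE savings per sex and
#' overall. For the four stratified rates the 95% CI bounds are applied to
#' every stratum simultaneously; perturbing the prevalence also re-derives
#' the initial state split, the at-risk denominator and the per-patient unit
#' cost from the perturbed prevalent count. For `relative_risk` the
#' dose-response CI bounds (applied in both arms) are used, and for
#' `discount_rate` the range in `discount_range` (default 0-4%).
#'
#' Note the direction of the risk parameter: the lower RR bound (stronger
#' protection) yields the *higher* savings, so `savings_at_lower` and
#' `savings_at_upper` — labelled by parameter bound — are not ordered;
#' `savings_low`/`savings_high` are the same two outputs ordered by value.
#'
#' @param ps A [parameter_set()].
#' @param sc A [scenario()] to compare against baseline.
#' @param parameter One of `incidence`, `prevalence`, `t2d_mortality`,
#'   `all_cause_mortality`, `relative_risk`, `discount_rate`.
#' @param cost_timing See [cumulative_discounted_nhe()].
#' @param discount_range Length-2 range used when `parameter` is
#'   `discount_rate`.
#' @return data.frame with one row per group (`men`, `women`, `all`):
#'   `parameter`, `group`, `savings_at_lower`, `savings_at_upper`,
#'   `expected_savings`, `savings_low`, `savings_high`, `range_width`.
#' @export
#' @examples
#' one_way(japan_2019(), scenario("scenario1", 160), "relative_risk")
one_way <- function(ps, sc, parameter, cost_timing = c("end", "start"),
                    discount_range = c(0, 0.04)) {
  stopifnot(inherits(ps, "parameter_set"), inherits(sc, "scenario"))
  cost_timing <- match.arg(cost_timing)
  if (!parameter %in% SENSITIVITY_PARAMETERS) {
    stop("one_way: unknown parameter '", parameter, "'; supported: ",
         paste(SENSITIVITY_PARAMETERS, collapse = ", "))
  }
  expected <- savings_by_group(ps, sc, cost_timing)
  at_bound <- function(bound) {
    if (parameter == "relative_risk") {
      rr_bound <- if (bound == "lower") "ci_low" else "ci_high"
      savings_by_group(ps, sc, cost_timing, rr_bound = rr_bound)
    } else if (parameter == "discount_rate") {
      ps2 <- ps
      ps2$discount_rate <- if (bound == "lower") min(discount_range)
                           else max(discount_range)
      savings_by_group(ps2, sc, cost_timing)
    } else {
      savings_by_group(perturb_parameter_set(ps, parameter, bound),
                       sc, cost_timing)
    }
  }
  lower <- at_bound("lower")
  upper <- at_bound("upper")
  groups <- names(expected)
  data.frame(
    parameter = parameter,
    group = groups,
    savings_at_lower = as.numeric(lower[groups]),
    savings_at_upper = as.numeric(upper[groups]),
    expected_savings = as.numeric(expected[groups]),
    savings_low = pmin(lower[groups], upper[groups]),
    savings_high = pmax(lower[groups], upper[groups]),
    range_width = abs(upper[groups] - lower[groups]),
    row.names = NULL
  )
}

#' Tornado table
#'
#' Runs [one_way()] for every supported parameter and orders parameters by
#' the width of the savings range they induce (descending; ties broken by
#' parameter name, so collapsed CIs give a stable alphabetical order).
#'
#' @inheritParams one_way
#' @return data.frame of stacked [one_way()] rows, ordered within each group
#'   by decreasing `range_width`.
#' @export
#' @examples
#' tor <- tornado(japan_2019(), scenario("scenario1", 160))
#' subset(tor, group == "men")$parameter[1]  # "relative_risk"
tornado <- function(ps, sc, cost_timing = c("end", "start"),
                    discount_range = c(0, 0.04)) {
  cost_timing <- match.arg(cost_timing)
  rows <- lapply(sort(SENSITIVITY_PARAMETERS), function(p) {
    one_way(ps, sc, p, cost_timing = cost_timing,
            discount_range = discount_range)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$group, -tab$range_width,
                   tab$parameter, method = "radix"), ]
  rownames(tab) <- NULL
  tab
}
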