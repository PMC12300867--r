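#' Dose-response relative risk per intake increment
#'
#' A relative risk for developing T2D associated with each fixed increment of
#' daily yogurt intake, with its 95% confidence bounds. The risk for an
#' arbitrary intake change is obtained by log-linear (power-law) extrapolation,
#' see [rr_for_intake_change()].
#'
#' @param rr Point relative risk per `increment` g/day (dimensionless, > 0).
#' @param increment Intake increment the risk refers to, in g/day.
#' @param ci_low,ci_high 95% confidence bounds, `0 < ci_low <= rr <= ci_high`.
#' @return A `dose_response` object (list with the four fields).
#' @export
#' @examples
#' dose_response(0.93, 50, 0.89, 0.97)
dose_response <- function(rr, increment = 50, ci_low = rr, ci_high = rr) {
  stopifnot(is.numeric(rr), length(rr) == 1, is.numeric(increment))
  if (increment <= 0) stop("dose_response: increment must be > 0")
  if (!(0 < ci_low && ci_low <= rr && rr <= ci_high)) {
    stop("dose_response: need 0 < ci_low <= rr <= ci_high")
  }
  structure(
    list(rr = rr, increment = increment, ci_low = ci_low, ci_high = ci_high),
    class = "dose_response"
  )
}

#' Assemble a parameter set
#'
#' Bundles the stratum-level epidemiological table, the stratum-level annual
#' outpatient cost table, the dose-response relative risk and the scalar model
#' settings (discount rate, horizon) into one validated object. Rates are
#' stored exactly as published (per 100,000) and converted to probabilities
#' only inside the transition-matrix builder, avoiding double rounding.
#'
#' @param strata `data.frame` with the columns listed in
#'   [read_parameter_set()]: one row per sex x age-band stratum with
#'   population, mean intake (g/day), and T2D incidence, prevalence, T2D
#'   mortality and all-cause mortality per 100,000 with CI bounds.
#' @param costs `data.frame` with columns `sex`, `age_band`,
#'   `annual_outpatient_nhe_usd`: annual outpatient national healthcare
#'   expenditure (USD) attributable to the stratum's prevalent T2D population.
#' @param dr A [dose_response()] object.
#' @param discount_rate Annual discount rate applied to costs (fraction/year).
#' @param horizon Number of annual cycles simulated.
#' @param validate If `TRUE` (default) the set must pass
#'   [validate_parameter_set()].
#' @return A `parameter_set` object.
#' @seealso [japan_2019()] for the built-in fixture.
#' @export
parameter_set <- function(strata, costs, dr,
                          discount_rate = 0.02, horizon = 10L,
                          validate = TRUE) {
  stopifnot(is.data.frame(strata), is.data.frame(costs),
            inherits(dr, "dose_response"))
  missing_cols <- setdiff(STRATA_COLUMNS, names(strata))
  if (length(missing_cols) > 0) {
    stop("parameter_set: strata table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  missing_cols <- setdiff(COST_COLUMNS, names(costs))
  if (length(missing_cols) > 0) {
    stop("parameter_set: cost table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  strata <- strata[, STRATA_COLUMNS]
  costs <- costs[, COST_COLUMNS]
  rownames(strata) <- rownames(costs) <- NULL
  ps <- structure(
    list(strata = strata, costs = costs, dose_response = dr,
         discount_rate = discount_rate, horizon = as.integer(horizon)),
    class = "parameter_set"
  )
  if (validate) {
    rep <- validate_parameter_set(ps)
    if (nrow(rep) > 0) {
      stop("parameter_set: invalid parameters:\n",
           paste(sprintf("  [%s] %s: %s", rep$stratum, rep$field, rep$message),
                 collapse = "\n"))
    }
  }
  ps
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf(
    "<parameter_set> %d strata, horizon %d y, discount %.1f%%, RR %.2f (%.2f-%.2f) per %g g/day\n",
    nrow(x$strata), x$horizon, 100 * x$discount_rate,
    x$dose_response$rr, x$dose_response$ci_low, x$dose_response$ci_high,
    x$dose_response$increment))
  print(x$strata[, c("sex", "age_band", "population", "mean_intake_g",
                     "incidence_per100k", "prevalence_per100k",
                     "t2d_mort_per100k", "allcause_mort_per100k")], ...)
  invisible(x)
}

#' Built-in Japan 2019 parameter set
#'
#' The published sex- and age-stratified inputs for the Japanese population
#' aged 40-79 years in 2019: population counts, mean intake of fermented milk
#' and probiotic beverages (the available proxy for yogurt intake, g/day), T2D
#' incidence, T2D prevalence, T2D mortality and all-cause mortality (each per
#' 100,000 with 95% CI), annual outpatient healthcare expenditure for diabetes
#' per stratum (2019 USD, converted at the 2019 average rate of 109.01 JPY/USD
#' at source), a dose-response relative risk of 0.93 (0.89-0.97) per 50 g/day,
#' a 2% annual discount rate and a 10-year horizon.
#'
#' @return A [parameter_set()] with 8 strata (2 sexes x 4 ten-year age bands).
#' @export
#' @examples
#' ps <- japan_2019()
#' sum(ps$strata$population)  # 66,958,000 persons aged 40-79 in 2019
japan_2019 <- function() {
  strata <- data.frame(
    sex = rep(c("men", "women"), each = 4),
    age_band = rep(c("40-49", "50-59", "60-69", "70-79"), 2),
    population = c(9374000, 8161000, 7930000, 7333000,
                   9147000, 8117000, 8302000, 8594000),
    mean_intake_g = c(24.5, 31.1, 34.4, 40.9, 34.1, 44.7, 47.3, 51.4),
    incidence_per100k = c(386.9, 520.9, 517.9, 317.7, 224.1, 327.5, 365.9, 303.0),
    incidence_lo = c(289.6, 406.6, 385.1, 224.6, 163.3, 244.7, 262.1, 220.4),
    incidence_hi = c(498.6, 658.2, 661.3, 418.3, 295.4, 430.3, 483.7, 395.8),
    prevalence_per100k = c(5716.5, 10032.7, 15065.7, 18541.9,
                           3310.0, 5957.5, 9303.4, 12210.5),
    prevalence_lo = c(4728.7, 8734.0, 13385.8, 16590.8,
                      2697.6, 5070.1, 8126.7, 10786.8),
    prevalence_hi = c(6726.4, 11449.3, 16975.4, 20761.4,
                      3992.1, 7038.2, 10724.5, 13856.9),
    t2d_mort_per100k = c(1.1, 3.5, 7.6, 17.0, 0.3, 0.9, 2.7, 8.9),
    t2d_mort_lo = c(1.0, 3.2, 7.0, 15.5, 0.3, 0.8, 2.5, 7.5),
    t2d_mort_hi = c(1.3, 3.8, 8.2, 18.4, 0.4, 1.0, 3.0, 9.9),
    allcause_mort_per100k = c(150.6, 390.6, 996.9, 2579.2,
                              88.2, 201.1, 439.3, 1205.0),
    allcause_mort_lo = c(147.9, 383.1, 979.4, 2538.1,
                         86.6, 197.4, 432.3, 1187.4),
    allcause_mort_hi = c(153.4, 398.5, 1015.4, 2622.3,
                         90.0, 205.1, 446.8, 1223.8)
  )
  costs <- data.frame(
    sex = strata$sex,
    age_band = strata$age_band,
    annual_outpatient_nhe_usd = c(320339533, 599793593, 1085266222, 1452129242,
                                  149412727, 284612996, 620583959, 985138127)
  )
  parameter_set(strata, costs, dose_response(0.93, 50, 0.89, 0.97),
                discount_rate = 0.02, horizon = 10L)
}

validation_row <- function(stratum, field, message) {
  data.frame(stratum = stratum, field = field, message = message)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the model inputs and reports each
#' violation with the stratum it occurs in, rather than failing on the first.
#' The invariants are: positive population and non-negative intake; every rate
#' below 100,000 per 100,000 and non-negative; T2D mortality not exceeding
#' all-cause mortality (so the death-from-other-causes probability is
#' non-negative); `ci_low <= point <= ci_high` for each rated field; strata
#' unique by sex x age band; exactly one cost entry per stratum with a
#' non-negative cost; valid dose-response ordering; non-negative discount
#' rate; horizon of at least one cycle.
#'
#' @param ps A [parameter_set()] (built with `validate = FALSE` if you expect
#'   violations).
#' @return A `data.frame` with columns `stratum`, `field`, `message`; zero
#'   rows when every invariant holds.
#' @export
#' @examples
#' nrow(validate_parameter_set(japan_2019()))  # 0
validate_parameter_set <- function(ps) {
  s <- ps$strata
  out <- list()
  add <- function(row) out[[length(out) + 1]] <<- row

  keys <- stratum_key(s)
  dup <- unique(keys[duplicated(keys)])
  for (k in dup) add(validation_row(k, "stratum", "duplicate sex x age_band"))

  bad_sex <- !s$sex %in% c("men", "women")
  for (k in keys[bad_sex]) {
    add(validation_row(k, "sex", "sex must be 'men' or 'women'"))
  }

  rated <- list(
    incidence = c("incidence_per100k", "incidence_lo", "incidence_hi"),
    prevalence = c("prevalence_per100k", "prevalence_lo", "prevalence_hi"),
    t2d_mortality = c("t2d_mort_per100k", "t2d_mort_lo", "t2d_mort_hi"),
    all_cause_mortality = c("allcause_mort_per100k", "allcause_mort_lo",
                            "allcause_mort_hi")
  )
  for (i in seq_len(nrow(s))) {
    k <- keys[i]
    if (!is.finite(s$population[i]) || s$population[i] <= 0) {
      add(validation_row(k, "population", "must be > 0"))
    }
    if (!is.finite(s$mean_intake_g[i]) || s$mean_intake_g[i] < 0) {
      add(validation_row(k, "mean_intake_g", "must be >= 0"))
    }
    for (field in names(rated)) {
      cols <- rated[[field]]
      pt <- s[[cols[1]]][i]; lo <- s[[cols[2]]][i]; hi <- s[[cols[3]]][i]
      if (any(!is.finite(c(pt, lo, hi)))) {
        add(validation_row(k, field, "non-finite value"))
        next
      }
      if (pt < 0 || pt >= 1e5) {
        add(validation_row(k, field, "rate must be in [0, 100000)"))
      }
      if (!(lo <= pt && pt <= hi)) {
        add(validation_row(k, field, "need ci_low <= point <= ci_high"))
      }
    }
    if (is.finite(s$t2d_mort_per100k[i]) && is.finite(s$allcause_mort_per100k[i]) &&
        s$t2d_mort_per100k[i] > s$allcause_mort_per100k[i]) {
      add(validation_row(k, "t2d_mortality",
                         "T2D mortality exceeds all-cause mortality"))
    }
  }

  ckeys <- stratum_key(ps$costs)
  for (k in setdiff(keys, ckeys)) {
    add(validation_row(k, "cost", "no cost entry for stratum"))
  }
  for (k in setdiff(ckeys, keys)) {
    add(validation_row(k, "cost", "cost entry without matching stratum"))
  }
  dupc <- unique(ckeys[duplicated(ckeys)])
  for (k in dupc) add(validation_row(k, "cost", "duplicate cost entry"))
  bad_cost <- !is.finite(ps$costs$annual_outpatient_nhe_usd) |
    ps$costs$annual_outpatient_nhe_usd < 0
  for (k in ckeys[bad_cost]) {
    add(validation_row(k, "cost", "annual_outpatient_nhe_usd must be >= 0"))
  }

  dr <- ps$dose_response
  if (!(0 < dr$ci_low && dr$ci_low <= dr$rr && dr$rr <= dr$ci_high)) {
    add(validation_row("(global)", "dose_response",
                       "need 0 < ci_low <= rr <= ci_high"))
  }
  if (dr$increment <= 0) {
    add(validation_row("(global)", "dose_response", "increment must be > 0"))
  }
  if (!is.finite(ps$discount_rate) || ps$discount_rate < 0) {
    add(validation_row("(global)", "discount_rate", "must be >= 0"))
  }
  if (!is.finite(ps$horizon) || ps$horizon < 1) {
    add(validation_row("(global)", "horizon", "must be >= 1"))
  }

  if (length(out) == 0) {
    return(data.frame(stratum = character(), field = character(),
                      message = character()))
  }
  do.call(rbind, out)
}
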