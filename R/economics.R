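#' Per-patient annual outpatient cost
#'
#' Derives the annual outpatient cost per prevalent T2D patient by dividing
#' the stratum's annual outpatient national healthcare expenditure by its
#' 2019 prevalent patient count (`population * prevalence / 100,000`).
#'
#' @param annual_outpatient_nhe_usd Annual outpatient expenditure for the
#'   stratum, USD/year.
#' @param stratum One row of a parameter set's `strata` table.
#' @return USD per patient-year.
#' @export
#' @examples
#' ps <- japan_2019()
#' per_patient_annual_cost(ps$costs$annual_outpatient_nhe_usd[1],
#'                         ps$strata[1, ])  # ~597.8 USD
per_patient_annual_cost <- function(annual_outpatient_nhe_usd, stratum) {
  stopifnot(nrow(stratum) == 1, is.numeric(annual_outpatient_nhe_usd))
  prevalent <- stratum$population * stratum$prevalence_per100k / 1e5
  if (prevalent <= 0) {
    stop("per_patient_annual_cost [", stratum_key(stratum),
         "]: zero prevalent population, per-patient cost undefined")
  }
  annual_outpatient_nhe_usd / prevalent
}

#' Discount factor
#'
#' `(1 + rate)^(-cycle_index)`: the weight applied to costs accrued in the
#' cycle starting `cycle_index` years into the simulation. Cycle 0 is
#' undiscounted.
#'
#' @param rate Annual discount rate (fraction/year, >= 0).
#' @param cycle_index Cycle index (>= 0), may be a vector.
#' @return Dimensionless factor(s) in (0, 1].
#' @export
#' @examples
#' discount_factor(0.02, 0:3)
discount_factor <- function(rate, cycle_index) {
  stopifnot(is.numeric(rate), length(rate) == 1, rate >= 0,
            all(cycle_index >= 0))
  (1 + rate) ^ (-cycle_index)
}

#' Cumulative discounted healthcare expenditure of a trace
#'
#' Accrues the per-patient annual cost over the chronic-T2D occupancy of a
#' cohort trace and discounts each cycle's accrual to present value. With the
#' default `timing = "end"`, cycle `t` (t = 0, ..., horizon-1) accrues
#' `occupancy[t+1, chronic] * cost * (1+rate)^(-t)`: the cost of a model year
#' is carried by the people in the chronic state at the end of that year
#' (newly diagnosed patients incur outpatient costs from their diagnosis
#' year) and the first year is undiscounted. `timing = "start"` uses
#' start-of-cycle occupancy instead (`occupancy[t, chronic]`), the
#' conventional start-of-cycle accrual. End-of-cycle accrual is the default
#' because it is the timing that reproduces the published expenditure
#' projections.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param cost_per_patient_year USD per patient-year, see
#'   [per_patient_annual_cost()].
#' @param rate Annual discount rate.
#' @param timing `"end"` (default) or `"start"`, see above.
#' @return Present-value USD over the traced horizon.
#' @export
cumulative_discounted_nhe <- function(trace, cost_per_patient_year, rate,
                                      timing = c("end", "start")) {
  stopifnot(inherits(trace, "cohort_trace"))
  timing <- match.arg(timing)
  h <- length(trace$incident_flow)
  if (h == 0) return(0)
  chronic <- switch(timing,
    end = trace$occupancy[2:(h + 1), "chronic_t2d"],
    start = trace$occupancy[1:h, "chronic_t2d"]
  )
  sum(chronic * cost_per_patient_year * discount_factor(rate, 0:(h - 1)))
}
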