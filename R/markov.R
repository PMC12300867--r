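#' Initial state occupancy of a stratum
#'
#' Splits the stratum population between the "healthy" and "chronic T2D"
#' states according to the 2019 T2D prevalence; both death states start
#' empty. Occupancy is expected-value (fractional persons).
#'
#' @param stratum One row of a parameter set's `strata` table.
#' @return Named numeric vector over [model_states()] summing to the
#'   population.
#' @export
#' @examples
#' initial_occupancy(japan_2019()$strata[1, ])
initial_occupancy <- function(stratum) {
  stopifnot(nrow(stratum) == 1)
  prevalent <- stratum$population * stratum$prevalence_per100k / 1e5
  stats::setNames(
    c(stratum$population - prevalent, prevalent, 0, 0),
    model_states()
  )
}

#' Annual transition matrix of a stratum
#'
#' Builds the 4x4 annual transition matrix over [model_states()] from the
#' stratum's published rates and a relative-risk multiplier on incidence.
#' The annual probability that a healthy person is diagnosed with T2D is
#'
#' `p(healthy -> chronic) = incidence / (100,000 - prevalence) * rr_multiplier`
#'
#' i.e. the incidence rate, published per 100,000 total population, is
#' converted to the at-risk (never-diagnosed) denominator before the
#' dose-response multiplier is applied. Death from other causes strikes both
#' living states with probability `(all-cause mortality - T2D mortality) /
#' 100,000`; death from T2D strikes the chronic state with probability
#' `T2D mortality / 100,000`. Diagnosed individuals never revert to healthy,
#' the two death states are absorbing, and a healthy person cannot die of T2D
#' within the year of diagnosis. Rates are used directly as annual
#' probabilities (no exponential rate-to-probability conversion); at these
#' magnitudes the difference is below 0.2% and this direct reading is the one
#' that reproduces the published projections.
#'
#' @param stratum One row of a parameter set's `strata` table.
#' @param rr_multiplier Multiplier on the incidence probability, typically a
#'   column of [scenario_rr_table()]; must be >= 0.
#' @return 4x4 row-stochastic matrix with states as dimnames.
#' @export
build_transition_matrix <- function(stratum, rr_multiplier = 1) {
  stopifnot(nrow(stratum) == 1, is.numeric(rr_multiplier),
            length(rr_multiplier) == 1)
  if (!is.finite(rr_multiplier) || rr_multiplier < 0) {
    stop("build_transition_matrix: rr_multiplier must be finite and >= 0")
  }
  p_inc <- stratum$incidence_per100k /
    (1e5 - stratum$prevalence_per100k) * rr_multiplier
  p_death_other <- (stratum$allcause_mort_per100k -
                      stratum$t2d_mort_per100k) / 1e5
  p_death_t2d <- stratum$t2d_mort_per100k / 1e5
  if (p_death_other < 0) {
    stop("build_transition_matrix [", stratum_key(stratum),
         "]: T2D mortality exceeds all-cause mortality")
  }
  p_stay_healthy <- 1 - p_inc - p_death_other
  p_stay_chronic <- 1 - p_death_t2d - p_death_other
  if (p_stay_healthy < 0) {
    stop("build_transition_matrix [", stratum_key(stratum),
         "]: healthy-row probabilities exceed 1")
  }
  if (p_stay_chronic < 0) {
    stop("build_transition_matrix [", stratum_key(stratum),
         "]: chronic-row probabilities exceed 1")
  }
  states <- model_states()
  m <- matrix(
    c(p_stay_healthy, p_inc,          0,           p_death_other,
      0,              p_stay_chronic, p_death_t2d, p_death_other,
      0,              0,              1,           0,
      0,              0,              0,           1),
    nrow = 4, byrow = TRUE, dimnames = list(states, states)
  )
  m
}

#' Trace a closed cohort through the model
#'
#' Deterministic expected-value trace: starting from the prevalence-based
#' split of [initial_occupancy()], occupancy is propagated through
#' [build_transition_matrix()] for `horizon` annual cycles. All transitions
#' are evaluated simultaneously from start-of-cycle occupancy; per-cycle
#' flows record the expected number of new diagnoses (healthy -> chronic)
#' and of T2D deaths (chronic -> death) in each cycle.
#'
#' @param stratum One row of a parameter set's `strata` table.
#' @param rr_multiplier Incidence multiplier, see [build_transition_matrix()].
#' @param horizon Number of annual cycles (>= 0; 0 returns the initial split
#'   only).
#' @return A `cohort_trace`: list with `occupancy` ((horizon+1) x 4 matrix,
#'   row `t+1` is occupancy after `t` cycles), `incident_flow` and
#'   `t2d_death_flow` (length-`horizon` vectors), and `population`.
#' @export
#' @examples
#' tr <- run_cohort(japan_2019()$strata[1, ], rr_multiplier = 1, horizon = 10)
#' rowSums(tr$occupancy)  # conservation: always the stratum population
run_cohort <- function(stratum, rr_multiplier = 1, horizon = 10) {
  stopifnot(horizon >= 0, horizon == round(horizon))
  horizon <- as.integer(horizon)
  m <- build_transition_matrix(stratum, rr_multiplier)
  occ <- matrix(0, nrow = horizon + 1, ncol = 4,
                dimnames = list(0:horizon, model_states()))
  occ[1, ] <- initial_occupancy(stratum)
  incident_flow <- t2d_death_flow <- numeric(horizon)
  for (t in seq_len(horizon)) {
    incident_flow[t] <- occ[t, "healthy"] * m["healthy", "chronic_t2d"]
    t2d_death_flow[t] <- occ[t, "chronic_t2d"] * m["chronic_t2d", "death_t2d"]
    occ[t + 1, ] <- occ[t, ] %*% m
  }
  structure(
    list(occupancy = occ, incident_flow = incident_flow,
         t2d_death_flow = t2d_death_flow, population = stratum$population),
    class = "cohort_trace"
  )
}

#' Cumulative flows of a cohort trace
#'
#' Total expected new T2D diagnoses, and total expected deaths from T2D,
#' over the traced horizon.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @return Expected persons (fractional).
#' @export
cumulative_incidence <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  sum(trace$incident_flow)
}

#' @rdname cumulative_incidence
#' @export
cumulative_t2d_deaths <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  sum(trace$t2d_death_flow)
}

#' Export a cohort trace as tidy tables
#'
#' @param trace A `cohort_trace`.
#' @return List of two data frames: `occupancy` (cycle, state, persons) and
#'   `flows` (cycle, flow, persons), suitable for writing or plotting.
#' @export
trace_tables <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  occ <- trace$occupancy
  cycles <- as.integer(rownames(occ))
  occupancy <- data.frame(
    cycle = rep(cycles, times = ncol(occ)),
    state = rep(colnames(occ), each = nrow(occ)),
    persons = as.vector(occ)
  )
  h <- length(trace$incident_flow)
  flows <- data.frame(
    cycle = rep(seq_len(h), 2),
    flow = rep(c("incident", "t2d_death"), each = h),
    persons = c(trace$incident_flow, trace$t2d_death_flow)
  )
  list(occupancy = occupancy, flows = flows)
}
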