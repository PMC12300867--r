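#' Specification for a synthetic parameter set
#'
#' Describes the sampling ranges for a random parameter set with the same
#' statistical structure as the Japan-2019 tables: strata with rates per
#' 100,000 whose T2D mortality never exceeds all-cause mortality, log-scale
#' symmetric CI bounds, a protective dose-response relative risk and positive
#' per-patient annual costs. Defaults mirror the ranges spanned by the
#' Japan-2019 fixture.
#'
#' @param n_strata Number of strata to generate.
#' @param population_range Persons per stratum.
#' @param intake_range Mean daily intake, g/day.
#' @param incidence_range,prevalence_range,t2d_mort_range,allcause_mort_range
#'   Rate ranges, per 100,000.
#' @param rr_range Dose-response relative risk per increment.
#' @param increment_g Intake increment of the relative risk, g/day.
#' @param ci_halfwidth_fraction Log-scale half width of generated CIs: bounds
#'   are `point * exp(-f)` and `point * exp(f)`.
#' @param cost_pp_range Per-patient annual outpatient cost, USD.
#' @param seed Integer seed; the generator draws a per-stratum stream from it
#'   so adding strata does not reshuffle earlier ones.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_strata = 8,
                           population_range = c(5e6, 1e7),
                           intake_range = c(20, 55),
                           incidence_range = c(200, 650),
                           prevalence_range = c(3000, 20000),
                           t2d_mort_range = c(0.3, 18),
                           allcause_mort_range = c(80, 2700),
                           rr_range = c(0.9, 0.96),
                           increment_g = 50,
                           ci_halfwidth_fraction = 0.2,
                           cost_pp_range = c(400, 1200),
                           seed = 1L) {
  ordered2 <- function(x, name) {
    if (length(x) != 2 || any(!is.finite(x)) || x[1] > x[2] || x[1] < 0) {
      stop("synthetic_spec: ", name, " must be a non-negative ordered pair")
    }
  }
  ordered2(population_range, "population_range")
  ordered2(intake_range, "intake_range")
  ordered2(incidence_range, "incidence_range")
  ordered2(prevalence_range, "prevalence_range")
  ordered2(t2d_mort_range, "t2d_mort_range")
  ordered2(allcause_mort_range, "allcause_mort_range")
  ordered2(rr_range, "rr_range")
  ordered2(cost_pp_range, "cost_pp_range")
  stopifnot(n_strata >= 1, increment_g > 0, ci_halfwidth_fraction >= 0)
  f <- ci_halfwidth_fraction
  # every sampled t2d mortality must admit an all-cause rate whose lower CI
  # bound still dominates the t2d upper CI bound
  if (t2d_mort_range[1] * exp(2 * f) > allcause_mort_range[2]) {
    stop("synthetic_spec: t2d_mort_range is incompatible with ",
         "allcause_mort_range (no feasible all-cause rate)")
  }
  if (prevalence_range[2] * exp(f) >= 1e5) {
    stop("synthetic_spec: prevalence upper CI bound would reach 100,000")
  }
  structure(
    list(n_strata = as.integer(n_strata),
         population_range = population_range, intake_range = intake_range,
         incidence_range = incidence_range,
         prevalence_range = prevalence_range,
         t2d_mort_range = t2d_mort_range,
         allcause_mort_range = allcause_mort_range,
         rr_range = rr_range, increment_g = increment_g,
         ci_halfwidth_fraction = f, cost_pp_range = cost_pp_range,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

stratum_stream_seed <- function(seed, i) {
  (as.integer(seed) + 104729L * as.integer(i)) %% .Machine$integer.max
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

#' Sample a random valid parameter set
#'
#' Draws a parameter set from a [synthetic_spec()]. Deterministic given the
#' spec's seed, with one RNG stream per stratum so the first `k` strata are
#' identical across specs that differ only in `n_strata`. The sampled set
#' always passes [validate_parameter_set()]: the all-cause mortality is drawn
#' above `t2d_mortality * exp(2f)` so that even the perturbed combinations
#' used by [one_way()] keep every transition probability non-negative, and
#' costs are drawn via a per-patient annual cost in `cost_pp_range`.
#'
#' @param spec A [synthetic_spec()].
#' @return A validated [parameter_set()].
#' @export
#' @examples
#' ps <- sample_parameter_set(synthetic_spec(n_strata = 4, seed = 42))
#' nrow(validate_parameter_set(ps))  # 0
sample_parameter_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  f <- spec$ci_halfwidth_fraction
  rows <- lapply(seq_len(spec$n_strata), function(i) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(stratum_stream_seed(spec$seed, i))
    t2dm <- runif1(spec$t2d_mort_range)
    acm_min <- max(spec$allcause_mort_range[1], t2dm * exp(2 * f))
    if (acm_min > spec$allcause_mort_range[2]) {
      stop("sample_parameter_set: no feasible all-cause mortality for ",
           "sampled t2d mortality ", signif(t2dm, 3))
    }
    acm <- stats::runif(1, acm_min, spec$allcause_mort_range[2])
    inc <- runif1(spec$incidence_range)
    prev <- runif1(spec$prevalence_range)
    data.frame(
      sex = if (i %% 2 == 1) "men" else "women",
      age_band = sprintf("band%02d", (i + 1) %/% 2),
      population = round(runif1(spec$population_range)),
      mean_intake_g = runif1(spec$intake_range),
      incidence_per100k = inc,
      incidence_lo = inc * exp(-f), incidence_hi = inc * exp(f),
      prevalence_per100k = prev,
      prevalence_lo = prev * exp(-f), prevalence_hi = prev * exp(f),
      t2d_mort_per100k = t2dm,
      t2d_mort_lo = t2dm * exp(-f), t2d_mort_hi = t2dm * exp(f),
      allcause_mort_per100k = acm,
      allcause_mort_lo = acm * exp(-f), allcause_mort_hi = acm * exp(f),
      cost_pp = runif1(spec$cost_pp_range)
    )
  })
  tab <- do.call(rbind, rows)
  costs <- data.frame(
    sex = tab$sex, age_band = tab$age_band,
    annual_outpatient_nhe_usd =
      tab$cost_pp * tab$population * tab$prevalence_per100k / 1e5
  )
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(stratum_stream_seed(spec$seed, 0L))
  rr <- runif1(spec$rr_range)
  dr <- dose_response(rr, spec$increment_g,
                      ci_low = rr * exp(-f / 10), ci_high = rr * exp(f / 10))
  parameter_set(tab[, STRATA_COLUMNS], costs, dr)
}

#' Monte Carlo microsimulation oracle
#'
#' Simulates `n_individuals` independent state paths through the same annual
#' transition matrix the deterministic engine uses, by per-cycle multinomial
#' draws from each transient state's row, and scales the resulting state
#' counts to the stratum population. This is the stochastic ground truth the
#' expected-value trace of [run_cohort()] should match to within Monte Carlo
#' error: each state's scaled occupancy is expected to lie within about three
#' reported standard errors of the deterministic trace at every cycle.
#'
#' @param stratum One row of a parameter set's `strata` table.
#' @param rr_multiplier Incidence multiplier, as in [run_cohort()].
#' @param horizon Number of annual cycles (>= 0).
#' @param n_individuals Number of simulated individuals (>= 1).
#' @param seed Integer seed for the draws.
#' @return List with `occupancy` and `se` ((horizon+1) x 4 matrices, persons
#'   scaled to the stratum population), `counts` (raw individual counts) and
#'   `n_individuals`.
#' @export
#' @examples
#' s <- japan_2019()$strata[1, ]
#' ms <- microsim_oracle(s, 1, horizon = 5, n_individuals = 2000, seed = 7)
#' max(abs(ms$occupancy - run_cohort(s, 1, 5)$occupancy) / (ms$se + 1e-9))
microsim_oracle <- function(stratum, rr_multiplier = 1, horizon = 10,
                            n_individuals = 10000, seed = 1L) {
  stopifnot(nrow(stratum) == 1, n_individuals >= 1, horizon >= 0)
  horizon <- as.integer(horizon)
  n <- as.integer(n_individuals)
  m <- build_transition_matrix(stratum, rr_multiplier)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  counts <- matrix(0L, nrow = horizon + 1, ncol = 4,
                   dimnames = list(0:horizon, model_states()))
  chronic0 <- stats::rbinom(1, n, stratum$prevalence_per100k / 1e5)
  counts[1, ] <- c(n - chronic0, chronic0, 0L, 0L)
  for (t in seq_len(horizon)) {
    nxt <- c(0L, 0L, 0L, 0L)
    for (state in 1:4) {
      k <- counts[t, state]
      if (k == 0) next
      if (state >= 3) {  # absorbing
        nxt[state] <- nxt[state] + k
      } else {
        nxt <- nxt + as.integer(stats::rmultinom(1, k, m[state, ]))
      }
    }
    counts[t + 1, ] <- nxt
  }
  phat <- counts / n
  # continuity-corrected proportion for the SE so rare states (zero observed
  # counts) still get a positive Monte Carlo error estimate
  ptilde <- (counts + 0.5) / (n + 1)
  list(
    occupancy = phat * stratum$population,
    se = stratum$population * sqrt(ptilde * (1 - ptilde) / n),
    counts = counts,
    n_individuals = n
  )
}
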