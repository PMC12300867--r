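# Minimal hand-built stratum for closed-form checks; rates chosen so the
# arithmetic is easy to reproduce on paper.
toy_stratum <- function(population = 10000,
                        intake = 30,
                        incidence = 1000, prevalence = 10000,
                        t2d_mort = 50, allcause_mort = 500) {
  data.frame(
    sex = "men", age_band = "40-49",
    population = population, mean_intake_g = intake,
    incidence_per100k = incidence,
    incidence_lo = incidence * 0.8, incidence_hi = incidence * 1.2,
    prevalence_per100k = prevalence,
    prevalence_lo = prevalence * 0.8, prevalence_hi = prevalence * 1.2,
    t2d_mort_per100k = t2d_mort,
    t2d_mort_lo = t2d_mort * 0.8, t2d_mort_hi = t2d_mort * 1.2,
    allcause_mort_per100k = allcause_mort,
    allcause_mort_lo = allcause_mort * 0.9, allcause_mort_hi = allcause_mort * 1.1
  )
}

# Compare a microsimulation with the deterministic trace using the binomial
# standard error implied by the deterministic state probabilities (the model
# under test); the simulation's own SE collapses when a rare state happens to
# draw few counts. The count-scale SE is floored at one individual: below
# that, +/-3 SE spans less than the discreteness of the simulation and the
# normal approximation to a near-Poisson count is meaningless.
microsim_z <- function(stratum, rr, horizon, n, seed) {
  tr <- run_cohort(stratum, rr, horizon)
  ms <- microsim_oracle(stratum, rr, horizon, n, seed)
  p <- tr$occupancy / stratum$population
  se_counts <- pmax(sqrt(n * p * (1 - p)), 1)
  abs(ms$counts - n * p) / se_counts
}

microsim_max_z <- function(stratum, rr, horizon, n, seed) {
  max(microsim_z(stratum, rr, horizon, n, seed))
}

toy_parameter_set <- function(strata = rbind(toy_stratum(),
                                             transform(toy_stratum(),
                                                       sex = "women")),
                              cost_pp = 600,
                              dr = dose_response(0.93, 50, 0.89, 0.97),
                              discount_rate = 0.02, horizon = 10) {
  costs <- data.frame(
    sex = strata$sex, age_band = strata$age_band,
    annual_outpatient_nhe_usd =
      cost_pp * strata$population * strata$prevalence_per100k / 1e5
  )
  parameter_set(strata, costs, dr, discount_rate, horizon)
}
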