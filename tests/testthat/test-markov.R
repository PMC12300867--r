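test_that("initial occupancy splits the population by prevalence", {
  ps <- japan_2019()
  occ <- initial_occupancy(ps$strata[1, ])
  expect_equal(unname(occ["chronic_t2d"]), 535864.71)
  expect_equal(unname(occ["healthy"]), 9374000 - 535864.71)
  expect_equal(sum(occ), 9374000)

  s <- toy_stratum(prevalence = 0)
  expect_equal(unname(initial_occupancy(s)["healthy"]), s$population)
  s <- toy_stratum(prevalence = 99999.999)
  expect_equal(unname(initial_occupancy(s)["chronic_t2d"]), s$population,
               tolerance = 1e-6)
})

test_that("transition matrix is row-stochastic with the published structure", {
  ps <- japan_2019()
  for (i in seq_len(nrow(ps$strata))) {
    for (rr in c(0, 0.5, 0.9, 1)) {
      m <- build_transition_matrix(ps$strata[i, ], rr)
      expect_equal(unname(rowSums(m)), rep(1, 4), tolerance = 1e-12)
      expect_true(all(m >= 0 & m <= 1))
      # absorbing death states, no reversion, no same-year healthy->T2D death
      expect_equal(unname(m[3, ]), c(0, 0, 1, 0))
      expect_equal(unname(m[4, ]), c(0, 0, 0, 1))
      expect_equal(m["chronic_t2d", "healthy"], 0)
      expect_equal(m["healthy", "death_t2d"], 0)
    }
  }

  # incidence probability: population-denominated rate moved to the at-risk
  # denominator, times the multiplier
  m70 <- ps$strata[ps$strata$sex == "men" & ps$strata$age_band == "70-79", ]
  m <- build_transition_matrix(m70, 1)
  expect_equal(m["healthy", "chronic_t2d"], 317.7 / (1e5 - 18541.9))
  expect_equal(m["healthy", "death_other"], (2579.2 - 17.0) / 1e5)
  expect_equal(m["chronic_t2d", "death_t2d"], 17.0 / 1e5)

  # degenerate cases
  m <- build_transition_matrix(toy_stratum(incidence = 0, t2d_mort = 0,
                                           allcause_mort = 0), 1)
  expect_equal(unname(m), diag(4))
  m <- build_transition_matrix(toy_stratum(), 0)
  expect_equal(m["healthy", "chronic_t2d"], 0)
  expect_equal(sum(m["healthy", ]), 1)

  bad <- toy_stratum()
  bad$t2d_mort_per100k <- bad$allcause_mort_per100k + 1
  expect_error(build_transition_matrix(bad, 1), "exceeds all-cause")
  expect_error(build_transition_matrix(toy_stratum(incidence = 99000), 2),
               "exceed 1")
  expect_error(build_transition_matrix(toy_stratum(), -0.1), "rr_multiplier")
})

test_that("cohort trace conserves persons and matches closed forms", {
  ps <- japan_2019()
  for (i in seq_len(nrow(ps$strata))) {
    tr <- run_cohort(ps$strata[i, ], 0.9, 10)
    expect_equal(unname(rowSums(tr$occupancy)),
                 rep(ps$strata$population[i], 11), tolerance = 1e-6)
    expect_true(all(tr$occupancy >= 0))
    # absorbing states never lose mass
    expect_true(all(diff(tr$occupancy[, "death_t2d"]) >= 0))
    expect_true(all(diff(tr$occupancy[, "death_other"]) >= 0))
    # cumulative T2D-death flow equals the terminal absorbing-state gain
    expect_equal(cumulative_t2d_deaths(tr),
                 tr$occupancy[11, "death_t2d"] - tr$occupancy[1, "death_t2d"],
                 ignore_attr = TRUE)
  }

  # horizon 0: initial row only, zero flows
  tr0 <- run_cohort(ps$strata[1, ], 1, 0)
  expect_equal(nrow(tr0$occupancy), 1)
  expect_equal(cumulative_incidence(tr0), 0)
  expect_equal(cumulative_t2d_deaths(tr0), 0)

  # no transitions at all: occupancy constant over cycles
  s <- toy_stratum(incidence = 0, t2d_mort = 0, allcause_mort = 0)
  tr <- run_cohort(s, 1, 5)
  expect_equal(tr$occupancy,
               matrix(rep(tr$occupancy[1, ], each = 6), nrow = 6,
                      dimnames = dimnames(tr$occupancy)))

  # zero mortality: cumulative incidence has the geometric closed form
  # H0 * (1 - (1 - p)^T)
  s <- toy_stratum(t2d_mort = 0, allcause_mort = 0)
  p <- s$incidence_per100k / (1e5 - s$prevalence_per100k)
  h0 <- s$population * (1 - s$prevalence_per100k / 1e5)
  tr <- run_cohort(s, 1, 10)
  expect_equal(cumulative_incidence(tr), h0 * (1 - (1 - p)^10),
               tolerance = 1e-12)
})

test_that("cumulative outcomes are monotone in the risk multiplier", {
  s <- japan_2019()$strata[3, ]
  rr_grid <- c(0.2, 0.5, 0.8, 0.9, 1)
  inc <- vapply(rr_grid,
                function(r) cumulative_incidence(run_cohort(s, r, 10)),
                numeric(1))
  dth <- vapply(rr_grid,
                function(r) cumulative_t2d_deaths(run_cohort(s, r, 10)),
                numeric(1))
  expect_true(all(diff(inc) > 0))
  expect_true(all(diff(dth) > 0))
})

test_that("trace exports tidy occupancy and flow tables", {
  tr <- run_cohort(japan_2019()$strata[1, ], 1, 10)
  tabs <- trace_tables(tr)
  expect_equal(nrow(tabs$occupancy), 11 * 4)
  expect_equal(nrow(tabs$flows), 10 * 2)
  expect_equal(sum(tabs$flows$persons[tabs$flows$flow == "incident"]),
               cumulative_incidence(tr))
})
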