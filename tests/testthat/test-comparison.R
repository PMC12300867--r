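test_that("run_scenario composes the pipeline deterministically", {
  ps <- japan_2019()
  b1 <- run_scenario(ps, baseline_scenario())
  b2 <- run_scenario(ps, baseline_scenario())
  expect_identical(b1, b2)
  expect_equal(nrow(b1), 8)
  expect_true(all(b1$cum_incidence > 0))
  expect_true(all(b1$cum_discounted_nhe_usd > 0))

  # a target below every stratum mean is indistinguishable from baseline
  low <- run_scenario(ps, scenario("low", 5))
  expect_equal(low$cum_incidence, b1$cum_incidence)
  expect_equal(low$cum_discounted_nhe_usd, b1$cum_discounted_nhe_usd)

  # intervention reduces all three outcomes in every stratum
  s1 <- run_scenario(ps, scenario("scenario1", 160))
  expect_true(all(s1$cum_incidence < b1$cum_incidence))
  expect_true(all(s1$cum_t2d_deaths < b1$cum_t2d_deaths))
  expect_true(all(s1$cum_discounted_nhe_usd < b1$cum_discounted_nhe_usd))
})

test_that("comparisons difference the arms and aggregate exactly", {
  ps <- japan_2019()
  b <- run_scenario(ps, baseline_scenario())
  s1 <- run_scenario(ps, scenario("scenario1", 160))
  cmp <- compare_scenarios(b, s1)

  expect_equal(cmp$by_stratum$prevented_incidence,
               b$cum_incidence - s1$cum_incidence)
  # identity comparison: all zeros
  self <- compare_scenarios(b, b)
  expect_equal(self$by_stratum$prevented_incidence, rep(0, 8))
  expect_equal(self$aggregated$saved_nhe_usd, rep(0, 3))
  # antisymmetry of the absolute fields
  rev <- compare_scenarios(s1, b)
  expect_equal(rev$by_stratum$prevented_incidence,
               -cmp$by_stratum$prevented_incidence)
  expect_equal(rev$by_stratum$saved_nhe_usd, -cmp$by_stratum$saved_nhe_usd)

  # aggregates are sums over strata, exactly
  agg <- cmp$aggregated
  expect_equal(agg$prevented_incidence[agg$group == "all"],
               sum(cmp$by_stratum$prevented_incidence))
  expect_equal(agg$prevented_incidence[agg$group == "men"],
               sum(cmp$by_stratum$prevented_incidence[
                 cmp$by_stratum$sex == "men"]))
  expect_equal(agg$saved_nhe_usd[agg$group == "all"],
               sum(agg$saved_nhe_usd[agg$group != "all"]))

  expect_error(compare_scenarios(b, s1[-1, ]), "different strata")
})

test_that("per-stratum prevented-incidence percentages track the naive RR
           reduction within two points", {
  ps <- japan_2019()
  b <- run_scenario(ps, baseline_scenario())
  for (target in c(160, 80)) {
    sc <- scenario(paste0("t", target), target)
    cmp <- compare_scenarios(b, run_scenario(ps, sc))
    naive <- 100 * (1 - scenario_rr_table(ps, sc)$rr_multiplier)
    expect_true(all(abs(cmp$by_stratum$prevented_incidence_pct - naive) < 2))
  }
})

test_that("report rendering writes the published table shapes", {
  dir <- withr::local_tempdir()
  ps <- japan_2019()
  b <- run_scenario(ps, baseline_scenario())
  cmp <- compare_scenarios(b, run_scenario(ps, scenario("scenario1", 160)))
  files <- render_report(dir, b, list(cmp))
  expect_true(all(file.exists(files)))

  base_tab <- utils::read.csv(file.path(dir, "baseline_projection.csv"))
  # 8 stratum rows plus one total row per sex
  expect_equal(nrow(base_tab), 10)
  expect_equal(sum(base_tab$age_band == "total"), 2)
  men_total <- base_tab[base_tab$sex == "men" & base_tab$age_band == "total", ]
  expect_equal(men_total$cum_incidence,
               sum(b$cum_incidence[b$sex == "men"]))

  prev_tab <- utils::read.csv(file.path(dir, "prevention_scenario1.csv"))
  expect_equal(nrow(prev_tab), 10)
  expect_true("prevented_incidence_pct" %in% names(prev_tab))

  expect_error(render_report(dir, b[0, ]), "empty")
})
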