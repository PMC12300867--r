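test_that("intake deltas floor at zero and vanish at baseline", {
  ps <- japan_2019()
  s1 <- scenario("scenario1", 160)
  expect_equal(intake_delta(ps$strata[1, ], s1), 160 - 24.5)
  expect_equal(
    intake_delta(ps$strata[ps$strata$sex == "women" &
                             ps$strata$age_band == "70-79", ],
                 scenario("scenario2", 80)),
    80 - 51.4)
  expect_equal(intake_delta(ps$strata, baseline_scenario()), rep(0, 8))
  # a target below the stratum mean leaves intake unchanged
  expect_equal(intake_delta(ps$strata[8, ], scenario("low", 10)), 0)
})

test_that("dose-response extrapolation is the power law per increment", {
  dr <- dose_response(0.93, 50, 0.89, 0.97)
  expect_equal(rr_for_intake_change(0, dr), 1.0)
  expect_equal(rr_for_intake_change(50, dr), 0.93)
  expect_equal(rr_for_intake_change(100, dr), 0.8649)
  expect_equal(rr_for_intake_change(135.5, dr), 0.821464482330088,
               tolerance = 1e-12)
  expect_error(rr_for_intake_change(-1, dr), "negative")
})

test_that("log-linearity: multiplicative in the intake change to 1e-12", {
  dr <- dose_response(0.93, 50, 0.89, 0.97)
  set.seed(101)
  for (i in 1:50) {
    a <- runif(1, 0, 200); b <- runif(1, 0, 200)
    expect_equal(rr_for_intake_change(a + b, dr),
                 rr_for_intake_change(a, dr) * rr_for_intake_change(b, dr),
                 tolerance = 1e-12)
  }
})

test_that("protective RR is monotone decreasing and bracketed by its CI", {
  dr <- dose_response(0.93, 50, 0.89, 0.97)
  deltas <- seq(0, 300, by = 10)
  rr <- rr_for_intake_change(deltas, dr)
  expect_true(all(diff(rr) < 0))
  for (d in c(25, 80, 135.5)) {
    expect_lt(rr_for_intake_change(d, dr, "ci_low"),
              rr_for_intake_change(d, dr))
    expect_gt(rr_for_intake_change(d, dr, "ci_high"),
              rr_for_intake_change(d, dr))
  }
})

test_that("scenario RR tables cover both references", {
  ps <- japan_2019()
  base_tab <- scenario_rr_table(ps, baseline_scenario())
  expect_equal(base_tab$rr_multiplier, rep(1, 8))

  s1 <- scenario_rr_table(ps, scenario("scenario1", 160))
  expect_equal(s1$rr_multiplier[1], 0.821464482330088, tolerance = 1e-12)
  s2 <- scenario_rr_table(ps, scenario("scenario2", 80))
  expect_equal(s2$rr_multiplier[1], 0.93^(55.5 / 50), tolerance = 1e-12)

  # zero-intake reference: baseline arm carries rr^(mean/increment), and the
  # ratio of scenario to baseline multipliers equals the baseline-referenced one
  z_base <- scenario_rr_table(ps, baseline_scenario(), reference = "zero")
  z_s1 <- scenario_rr_table(ps, scenario("scenario1", 160), reference = "zero")
  expect_equal(z_base$rr_multiplier, 0.93^(ps$strata$mean_intake_g / 50))
  expect_equal(z_s1$rr_multiplier / z_base$rr_multiplier, s1$rr_multiplier,
               tolerance = 1e-12)
})

test_that("scenario constructor validates its inputs", {
  expect_error(scenario("s", -5), ">= 0")
  expect_error(scenario("s"), "target_intake")
  expect_identical(baseline_scenario()$target_intake, NULL)
})
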