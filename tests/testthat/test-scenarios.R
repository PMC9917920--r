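test_that("a case-free wave series yields the identity scenario", {
  w <- data.frame(week_start = as.Date("2020-01-06") + 7 * (0:9),
                  new_cases = 0, emergency_declared = FALSE)
  m <- build_pandemic_scenario(w, pandemic_response_params())
  expect_true(all(as.matrix(as.data.frame(m)[, -1]) == 1))
  w$new_cases[1] <- -5
  expect_error(build_pandemic_scenario(w, pandemic_response_params()),
               ">= 0")
})

test_that("a saturating wave approaches the maximum impact and equal waves
           habituate by the adaptation halflife", {
  w <- data.frame(week_start = as.Date("2020-01-06"), new_cases = 1e9,
                  emergency_declared = FALSE)
  pp <- pandemic_response_params(case_saturation = 2000,
                                 max_demand_impact = 0.4,
                                 max_supply_impact = 0.1,
                                 emergency_boost = 0,
                                 adaptation_halflife = 26)
  m <- build_pandemic_scenario(w, pp)
  expect_equal(m$d_care_seeking[1], 1 - 0.4, tolerance = 1e-5)

  # two identical single-week pulses 20 weeks apart, halflife 20:
  # the second peak impact is exactly half the first
  w2 <- data.frame(week_start = as.Date("2020-01-06") + 7 * (0:39),
                   new_cases = 0, emergency_declared = FALSE)
  w2$new_cases[c(1, 21)] <- 1e9
  pp2 <- pandemic_response_params(case_saturation = 2000,
                                  max_demand_impact = 0.4,
                                  max_supply_impact = 0,
                                  emergency_boost = 0,
                                  adaptation_halflife = 20)
  m2 <- build_pandemic_scenario(w2, pp2)
  imp <- 1 - m2$d_care_seeking
  expect_equal(imp[21] / imp[1], 0.5, tolerance = 1e-6)
})

test_that("peak impact is non-increasing across successive equal waves and
           multipliers stay in [0,1]", {
  set.seed(31)
  for (i in 1:10) {
    w <- data.frame(week_start = as.Date("2020-01-06") + 7 * (0:59),
                    new_cases = 0, emergency_declared = FALSE)
    peaks <- c(5, 25, 45)
    w$new_cases[peaks] <- runif(1, 100, 1e5)
    pp <- pandemic_response_params(
      case_saturation = runif(1, 100, 5000),
      max_demand_impact = runif(1, 0, 1),
      max_supply_impact = runif(1, 0, 1),
      emergency_boost = runif(1, 0, 0.5),
      adaptation_halflife = runif(1, 5, 80))
    m <- build_pandemic_scenario(w, pp)
    mm <- as.matrix(as.data.frame(m)[, -1])
    expect_true(all(mm >= 0 & mm <= 1))
    imp <- 1 - m$d_care_seeking
    expect_true(all(diff(imp[peaks]) <= 1e-12))
  }
})

test_that("the earthquake profile drops immediately, recovers linearly, and
           integrates to its closed form", {
  m <- build_earthquake_scenario(40, 5, 0.8, 10)
  expect_equal(m$d_continuous[6], 0.2)            # at the shock
  expect_equal(m$d_continuous[11], 0.6)           # halfway through recovery
  expect_true(all(m$d_continuous[1:5] == 1))      # before the shock
  expect_identical(m$d_continuous, m$s_procedures)
  expect_equal(sum(1 - m$d_continuous), 0.8 * (10 + 1) / 2,
               tolerance = 1e-9)
  m0 <- build_earthquake_scenario(40, 5, 0, 10)
  expect_true(all(as.matrix(as.data.frame(m0)[, -1]) == 1))
})

test_that("the financial crisis is purely demand-side with the stated hold
           depth", {
  m <- build_financial_crisis_scenario(60, 5, 0.3, 10, 8)
  expect_true(all(m$s_outpatient == 1 & m$s_procedures == 1 &
                  m$s_biologic == 1))
  expect_equal(m$d_care_seeking[10], 0.7)  # mid-hold
  m0 <- build_financial_crisis_scenario(20, 5, 0.3, 0, 0)
  expect_equal(sum(m0$d_care_seeking != 1), 1)  # single ramp week
})

test_that("wave series round-trip through CSV with logical emergency
           flags", {
  w <- synthetic_wave_series()
  f <- tempfile(fileext = ".csv")
  utils::write.csv(transform(w, emergency_declared =
                               tolower(emergency_declared)),
                   f, row.names = FALSE, quote = FALSE)
  w2 <- read_covid_waves(f)
  expect_equal(w2$new_cases, w$new_cases)
  expect_identical(w2$emergency_declared, w$emergency_declared)
  expect_identical(w2$week_start, w$week_start)
})
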