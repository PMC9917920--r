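const_series <- function(value, n = 9, start = as.Date("2021-03-01")) {
  ws <- start + 7 * (seq_len(n) - 1)
  z <- rep(0, n)
  demand_series(ws, new_patients = rep(value, n), total_patients = z,
                outpatient_visits = z, procedures = z, biologics = z,
                vedolizumab_infusions = z, new_vedolizumab_starts = z)
}

test_that("the normalized monthly misfit has the stated arithmetic", {
  obs <- const_series(10)
  expect_equal(calibration_objective(obs, obs, c(new_patients = 1)), 0)
  sim <- const_series(12)
  expect_equal(calibration_objective(sim, obs, c(new_patients = 1)),
               (2 / 10)^2, tolerance = 1e-12)
  # zero-weight channels are ignored; weights scale linearly
  expect_equal(calibration_objective(sim, obs, c(new_patients = 1,
                                                 procedures = 0)),
               0.04, tolerance = 1e-12)
  expect_equal(calibration_objective(sim, obs, c(new_patients = 3)),
               3 * 0.04, tolerance = 1e-12)
  # channel order is irrelevant
  o1 <- suppressWarnings(
    calibration_objective(sim, obs, c(new_patients = 1, total_patients = 2)))
  o2 <- suppressWarnings(
    calibration_objective(sim, obs, c(total_patients = 2, new_patients = 1)))
  expect_identical(o1, o2)
})

test_that("zero-mean observed channels are excluded with a warning and
           disjoint series are an error", {
  obs <- const_series(10)
  sim <- const_series(12)
  expect_warning(
    v <- calibration_objective(sim, obs, c(procedures = 1)),
    "zero observed mean")
  expect_equal(v, 0)
  far <- const_series(10, start = as.Date("2023-01-02"))
  expect_error(calibration_objective(sim, far, c(new_patients = 1)),
               "overlap")
})

test_that("collapsed bounds return the point with its objective", {
  ag <- toy_population(n_agents = 300, seed = 12)
  p <- default_pathway_parameters()
  obs <- run_simulation(ag, p, horizon = 16, seed = 4,
                        start_date = as.Date("2015-01-05"))
  tgt <- calibration_target("toy", "pre_covid", obs,
                            range = range(obs$week_start))
  fit <- fit_baseline_growth(tgt, ag, p,
                             bounds = list(growth = c(1.05, 1.05)),
                             seed = 1, replicates = 2,
                             channel_weights = c(total_patients = 1))
  expect_equal(unname(fit$par), 1.05)
  expect_true(is.finite(fit$objective_value))
  expect_equal(fit$phase, "pre_covid")
  expect_error(
    fit_baseline_growth(tgt, ag, p, bounds = list(growth = c(1.1, 1.0)),
                        seed = 1),
    "upper < lower")
})

test_that("fitting the emergency boost against an emergency-free wave
           series is flagged unidentifiable", {
  ag <- toy_population(n_agents = 200, seed = 12)
  p <- quiet_params()
  waves <- data.frame(week_start = as.Date("2020-01-06") + 7 * (0:7),
                      new_cases = c(0, 0, 500, 800, 400, 100, 0, 0),
                      emergency_declared = FALSE)
  obs <- run_simulation(ag, p, horizon = 8, seed = 4,
                        start_date = as.Date("2020-01-06"))
  tgt <- calibration_target("toy", "covid", obs,
                            range = range(obs$week_start))
  expect_warning(
    fit <- fit_disruption_response(
      tgt, waves, ag, p, template = pandemic_response_params(),
      bounds = list(emergency_boost = c(0, 0.5)),
      warmup_start = as.Date("2020-01-06"), seed = 2, n_starts = 2,
      replicates = 2, maxit = 15,
      channel_weights = c(outpatient_visits = 1)),
    "unidentifiable")
  expect_equal(fit$diagnostics$unidentifiable, "emergency_boost")
  expect_equal(fit$phase, "covid")
})
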