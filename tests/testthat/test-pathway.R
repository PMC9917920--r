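test_that("the incidence process scales geometrically with the yearly
           growth factor", {
  p <- default_pathway_parameters()
  p$growth <- 1
  expect_equal(advance_incidence(p, 0:199),
               rep(p$symptom_onset_hazard, 200))
  p$growth <- 1.1
  expect_equal(advance_incidence(p, 52), p$symptom_onset_hazard * 1.1)
  expect_equal(advance_incidence(p, 26), p$symptom_onset_hazard * sqrt(1.1))
  expect_error(advance_incidence(p, -1), ">= 0")
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(pathway_parameters(
    symptom_onset_hazard = 1.5, growth = 1, care_seeking_hazard = 0.3,
    diagnosis_probability = 0.8,
    visit_interval = c(mild_moderate = 8, moderate_severe = 4),
    procedure_interval = c(mild_moderate = 26, moderate_severe = 13),
    biologic_interval = 8, biologic_initiation_hazard = 0,
    severity_progression_hazard = 0), "probability")
  expect_error({
    p <- default_pathway_parameters()
    pathway_parameters(
      symptom_onset_hazard = 0.1, growth = 1, care_seeking_hazard = 0.3,
      diagnosis_probability = 0.8,
      visit_interval = c(mild_moderate = 0.5, moderate_severe = 4),
      procedure_interval = p$procedure_interval,
      biologic_interval = 8, biologic_initiation_hazard = 0,
      severity_progression_hazard = 0)
  }, ">= 1 week")
  expect_equal(annual_to_weekly(0), 0)
  # 52 weekly hazards compound to just over the annual probability
  expect_equal(52 * annual_to_weekly(0.05), 0.05, tolerance = 0.03)
  expect_equal(1 - (1 - annual_to_weekly(0.05))^52, 0.05, tolerance = 1e-12)
})

test_that("a zero-hazard asymptomatic agent is a fixed point of the weekly
           update", {
  st <- lone_biologic_agent()
  st$state <- "undiagnosed_asymptomatic"
  st$treatment <- "none"
  r <- step_agent(st, quiet_params(), week = 0)
  expect_equal(r$state$state, "undiagnosed_asymptomatic")
  expect_true(all(r$events == 0))
})

test_that("a due biologic agent emits one prescription and resets its
           timer", {
  r <- step_agent(lone_biologic_agent(interval = 8), quiet_params(), week = 0)
  expect_equal(r$events[["biologics"]], 1)
  expect_equal(r$events[["new_biologic_starts"]], 0)  # already on biologic
  expect_equal(r$state$weeks_since_biologic, 1)       # reset then advanced
})

test_that("suppressed demand defers events instead of delivering them", {
  p <- quiet_params()
  p$care_seeking_hazard <- 1
  st <- lone_biologic_agent()
  st$state <- "symptomatic_seeking_care"
  st$treatment <- "none"
  st$weeks_since_onset <- 0
  r <- step_agent(st, p, demand_multiplier = c(care_seeking = 0,
                                               continuous_care_visits = 1,
                                               biologic_refill = 1),
                  week = 0)
  expect_equal(r$events[["deferred_care_seeking"]], 1)
  expect_equal(r$events[["outpatient_visits"]], 0)
  expect_equal(r$state$state, "symptomatic_seeking_care")
})

test_that("with jitter off a lone biologic patient is served exactly every
           interval", {
  s <- run_simulation(lone_biologic_agent(interval = 8), quiet_params(),
                      horizon = 33, seed = 1)
  fired <- which(s$biologics > 0) - 1  # 0-based weeks
  expect_equal(fired, c(0, 8, 16, 24, 32))
  expect_true(all(s$biologics[fired + 1] == 1))
})

test_that("diagnosed patients never return to the undiagnosed stage and the
           diagnosed total is nondecreasing", {
  ag <- toy_population(n_agents = 1000, seed = 21)
  p <- default_pathway_parameters()
  p$symptom_onset_hazard <- 0.002
  s <- run_simulation(ag, p, horizon = 80, seed = 13, return_state = TRUE)
  expect_true(all(diff(s$total_patients) >= 0))
  st <- attr(s, "state")$engine
  init <- match(ag$state, c("undiagnosed_asymptomatic",
                            "symptomatic_seeking_care",
                            "diagnosed_continuous_care")) - 1L
  expect_true(all(st$stage >= 0))
  # anyone who started diagnosed is still diagnosed
  expect_true(all(st$stage[init == 2L] == 2L))
})
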