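test_that("apply_capacity arithmetic: slack, rationing, and abandonment", {
  cm <- capacity_model(c(outpatient_visits = 100, procedures = 4,
                         biologic_dispensing = Inf))
  r <- apply_capacity(c(outpatient_visits = 10, procedures = 10,
                        biologic_dispensing = 3), cm)
  expect_equal(unname(r$served["outpatient_visits"]), 10)
  expect_equal(unname(r$served["procedures"]), 4)
  expect_equal(unname(r$capacity$backlog["procedures"]), 6)
  expect_equal(unname(r$capacity$backlog["outpatient_visits"]), 0)

  cm2 <- capacity_model(c(outpatient_visits = 1, procedures = 1,
                          biologic_dispensing = 1), abandonment_rate = 1)
  r2 <- apply_capacity(c(outpatient_visits = 10, procedures = 10,
                         biologic_dispensing = 10), cm2)
  expect_equal(unname(r2$capacity$backlog), c(0, 0, 0))
  expect_equal(unname(r2$abandoned), c(9, 9, 9))
})

test_that("an identity scenario with unconstrained capacity is bitwise equal
           to the baseline run", {
  ag <- toy_population(n_agents = 1500, seed = 8)
  p <- default_pathway_parameters()
  base <- run_simulation(ag, p, horizon = 40, seed = 9)
  ident <- run_simulation(ag, p, modifiers = identity_scenario(40),
                          capacity = capacity_model(), horizon = 40, seed = 9)
  expect_identical(as.data.frame(base), as.data.frame(ident))
})

test_that("an empty population yields an all-zero series of the requested
           length", {
  ag <- toy_population(n_agents = 100)[0, ]
  s <- run_simulation(ag, default_pathway_parameters(), horizon = 7, seed = 1)
  expect_equal(nrow(s), 7)
  expect_true(all(as.matrix(as.data.frame(s)[, -1]) == 0))
})

test_that("a modifier series shorter than the horizon is an error", {
  ag <- toy_population(n_agents = 100)
  expect_error(
    run_simulation(ag, default_pathway_parameters(),
                   modifiers = identity_scenario(10), horizon = 20, seed = 1),
    "covers 10 weeks")
})

test_that("a one-week supply blackout zeroes the channel and pushes its
           demand into the backlog", {
  ag <- toy_population(n_agents = 1500, seed = 8)
  p <- default_pathway_parameters()
  mod <- identity_scenario(30)
  mod$s_procedures[11] <- 0  # 0-based week 10
  s <- run_simulation(ag, p, modifiers = mod, horizon = 30, seed = 9)
  d <- attr(s, "diagnostics")
  expect_equal(s$procedures[11], 0)
  expect_gt(d$backlog_procedures[11], 0)
  expect_gt(s$procedures[10], 0)
})

test_that("the backlog conservation identity holds every week under shocks,
           finite capacity, and abandonment", {
  ag <- toy_population(total = 20000, n_agents = 3000, seed = 3)
  p <- default_pathway_parameters()
  mod <- identity_scenario(60)
  mod$s_procedures[11:18] <- 0.05
  mod$s_outpatient[11:18] <- 0.5
  cap <- capacity_model(c(outpatient_visits = 2000, procedures = 700,
                          biologic_dispensing = 500),
                        backlog_service_rate = 0.5, abandonment_rate = 0.02)
  s <- run_simulation(ag, p, modifiers = mod, capacity = cap, horizon = 60,
                      seed = 42)
  d <- attr(s, "diagnostics")
  for (sv in c("outpatient", "procedures", "biologic")) {
    gap <- d[[paste0("cum_demanded_", sv)]] -
      d[[paste0("cum_served_", sv)]] -
      d[[paste0("backlog_", sv)]] -
      d[[paste0("cum_abandoned_", sv)]]
    expect_lt(max(abs(gap)), 1e-6)
  }
})

test_that("rapid backlog alleviation creates larger post-recovery
           oscillations than gradual alleviation", {
  ag <- toy_population(total = 20000, n_agents = 5000, seed = 3,
                       initial_states = list(undiagnosed = 0.1,
                                             symptomatic = 0,
                                             severe = 0.3, biologic = 0.25))
  p <- default_pathway_parameters()
  mod <- identity_scenario(60)
  mod$s_procedures[11:18] <- 0.05
  amp <- function(rate) {
    cap <- capacity_model(c(outpatient_visits = Inf, procedures = 1300,
                            biologic_dispensing = Inf),
                          backlog_service_rate = rate)
    s <- run_simulation(ag, p, modifiers = mod, capacity = cap,
                        horizon = 60, seed = 42)
    post <- s$procedures[19:44]
    max(post) - min(post)
  }
  expect_gt(amp(0.9), amp(0.1))
})

test_that("ensembles are reproducible with ordered five-number summaries", {
  ag <- toy_population(n_agents = 500, seed = 2)
  spec <- list(agents = ag, params = default_pathway_parameters(),
               horizon = 20)
  one <- run_ensemble(spec, n_runs = 1, base_seed = 7)
  expect_true(all(one$min == one$max))
  e1 <- run_ensemble(spec, n_runs = 5, base_seed = 7)
  e2 <- run_ensemble(spec, n_runs = 5, base_seed = 7)
  expect_identical(e1, e2)
  expect_true(all(e1$min <= e1$q1 & e1$q1 <= e1$median &
                  e1$median <= e1$q3 & e1$q3 <= e1$max))
  expect_equal(attr(e1, "n_runs"), 5)
})

test_that("monthly aggregation averages weeks by the calendar month of
           their start date", {
  ws <- as.Date("2021-03-01") + 7 * (0:3)   # four Mondays inside March
  s <- demand_series(ws, new_patients = 1:4, total_patients = rep(1, 4),
                     outpatient_visits = rep(0, 4), procedures = rep(0, 4),
                     biologics = rep(0, 4), vedolizumab_infusions = rep(0, 4),
                     new_vedolizumab_starts = rep(0, 4))
  m <- aggregate_monthly(s)
  expect_equal(nrow(m), 1)
  expect_equal(m$new_patients, 2.5)

  ws2 <- as.Date("2021-03-22") + 7 * (0:3)  # straddles March/April
  s2 <- demand_series(ws2, new_patients = c(1, 2, 3, 4),
                      total_patients = rep(5, 4),
                      outpatient_visits = rep(0, 4), procedures = rep(0, 4),
                      biologics = rep(0, 4),
                      vedolizumab_infusions = rep(0, 4),
                      new_vedolizumab_starts = rep(0, 4))
  m2 <- aggregate_monthly(s2)
  expect_equal(nrow(m2), 2)
  expect_equal(m2$new_patients, c(mean(c(1, 2)), mean(c(3, 4))))
  expect_true(all(m2$total_patients == 5))
})
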