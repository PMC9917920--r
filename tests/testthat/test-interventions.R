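test_that("the packaged catalogue carries the six interventions with their
           published impact values", {
  cat6 <- load_intervention_catalog()
  expect_length(cat6, 6)
  expect_equal(cat6[["physician outreach"]]$demand_impact, 0.15)
  expect_equal(cat6[["system social signaling"]]$demand_impact, 0.40)
  expect_equal(cat6[["national confidence building"]]$demand_impact, 0.60)
  expect_equal(cat6[["simple navigation assistance"]]$supply_impact, 0.05)
  expect_equal(cat6[["simple navigation assistance"]]$demand_impact, 0.15)
  expect_equal(cat6[["barrier elimination"]]$supply_impact, 0.40)
  expect_equal(cat6[["barrier elimination"]]$demand_impact, 0.40)
  expect_equal(cat6[["emergency response infrastructure"]]$supply_impact,
               0.60)
  expect_equal(cat6[["emergency response infrastructure"]]$demand_impact,
               0.55)
  # messaging interventions act on demand only
  for (nm in c("physician outreach", "system social signaling",
               "national confidence building")) {
    expect_true(is.na(cat6[[nm]]$supply_impact))
  }
})

test_that("interventions close their impact fraction of the disruption gap
           and compose commutatively on the residual", {
  cat6 <- load_intervention_catalog()
  dis <- scenario_modifiers(4, d_care_seeking = 0, d_continuous = 0,
                            d_biologic = 0)
  one <- apply_interventions(dis, cat6[["national confidence building"]])
  expect_equal(one$d_care_seeking, rep(0.6, 4))

  two <- apply_interventions(dis, list(cat6[["barrier elimination"]],
                                       cat6[["system social signaling"]]))
  expect_equal(two$d_care_seeking, rep(1 - 0.6 * 0.6, 4))

  # nothing to restore at baseline
  base <- identity_scenario(4)
  expect_identical(as.data.frame(apply_interventions(base, cat6)),
                   as.data.frame(base))
})

test_that("application order never matters (residual-gap composition is
           commutative)", {
  set.seed(17)
  for (i in 1:10) {
    impacts <- runif(3)
    ivs <- lapply(seq_along(impacts), function(j) {
      intervention_spec(paste0("iv", j), supply_impact = runif(1),
                        demand_impact = impacts[j],
                        supply_targets = c("s_outpatient", "s_procedures"),
                        demand_targets = c("d_care_seeking", "d_biologic"))
    })
    dis <- scenario_modifiers(6, d_care_seeking = runif(6),
                              d_biologic = runif(6),
                              s_outpatient = runif(6),
                              s_procedures = runif(6))
    a <- apply_interventions(dis, ivs)
    b <- apply_interventions(dis, rev(ivs))
    expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-12)
    mm <- as.matrix(as.data.frame(a)[, -1])
    expect_true(all(mm <= 1 + 1e-12))
  }
})

test_that("demand-only interventions never alter supply multipliers, zero
           impact is idempotent, and full impact restores baseline", {
  dis <- scenario_modifiers(5, d_care_seeking = 0.2, s_procedures = 0.3)
  msg <- intervention_spec("messaging", supply_impact = NA,
                           demand_impact = 0.4)
  r <- apply_interventions(dis, msg)
  expect_identical(r$s_procedures, dis$s_procedures)
  zero <- intervention_spec("noop", demand_impact = 0)
  expect_identical(as.data.frame(apply_interventions(dis, zero)),
                   as.data.frame(dis))
  full <- intervention_spec("full", demand_impact = 1)
  expect_equal(apply_interventions(dis, full)$d_care_seeking, rep(1, 5))
})

test_that("interventions respect their active window", {
  dis <- scenario_modifiers(6, d_care_seeking = 0)
  iv <- intervention_spec("windowed", demand_impact = 0.5,
                          active_window = c(2, 3))
  r <- apply_interventions(dis, iv)
  expect_equal(r$d_care_seeking, c(0, 0, 0.5, 0.5, 0, 0))
})

test_that("overriding packaged impact values warns", {
  f <- tempfile(fileext = ".csv")
  df <- utils::read.csv(system.file("extdata", "interventions.csv",
                                    package = "ibddemand"))
  df$demand_impact[1] <- 0.99
  utils::write.csv(df, f, row.names = FALSE, quote = TRUE)
  expect_warning(load_intervention_catalog(f), "differ from the packaged")
})
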