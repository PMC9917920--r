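# Shared builders for test fixtures: everything is generated in code.

toy_targets <- function(total = 8000, region = "toy") {
  marginal_target_set(
    region, total,
    sex_proportions = c(male = 0.5, female = 0.5),
    condition_proportions = c(UC = 0.5, CD = 0.5),
    age_targets = data.frame(
      condition = rep(c("UC", "CD"), each = 2),
      sex = rep(c("male", "female"), 2),
      mean = 50, sd = 12
    ),
    age_bounds = c(18, 74)
  )
}

toy_population <- function(total = 8000, n_agents = 2000, seed = 3, ...) {
  generate_population(toy_targets(total), n_agents = n_agents, seed = seed,
                      ...)
}

# single diagnosed agent on biologic maintenance, timers due now
lone_biologic_agent <- function(interval = 8) {
  data.frame(
    agent_id = 1L, region = "toy", sex = "male", age = 40, condition = "UC",
    severity = "mild_moderate", state = "diagnosed_continuous_care",
    treatment = "biologic", weight = 1, propensity = 1,
    next_visit_due = 1e9, weeks_since_procedure = 0,
    procedure_threshold = 1e9, weeks_since_biologic = interval,
    biologic_threshold = interval, ever_biologic = TRUE,
    weeks_since_onset = NA_real_
  )
}

# pathway parameters with all stochastic transitions switched off
quiet_params <- function() {
  p <- default_pathway_parameters()
  p$symptom_onset_hazard <- 0
  p$severity_progression_hazard <- 0
  p$biologic_initiation_hazard <- 0
  p$interval_jitter_sd <- 0
  p
}

# --- calibration parameter-recovery harness (shared with acceptance) -------
# A stationary-utilization population whose claims emulation is structurally
# matched to the simulator: all mild severity, no progression/initiation, no
# interval jitter, symptomatic pool primed at its steady state, and the
# claims prevalence anchored to the realized diagnosed weight.

harness_agents <- function() {
  tg <- marginal_target_set(
    "harness", 40000,
    sex_proportions = c(male = 0.5, female = 0.5),
    condition_proportions = c(UC = 0.5, CD = 0.5),
    age_targets = data.frame(
      condition = rep(c("UC", "CD"), each = 2),
      sex = rep(c("male", "female"), 2), mean = 50, sd = 12
    ),
    age_bounds = c(18, 74)
  )
  generate_population(tg, n_agents = 20000, seed = 101,
                      initial_states = list(undiagnosed = 0.40,
                                            symptomatic = 0.0042,
                                            severe = 0, biologic = 0.25))
}

harness_params <- function(onset = 2.5e-3, growth = 1.08) {
  p <- default_pathway_parameters()
  p$severity_progression_hazard <- 0
  p$biologic_initiation_hazard <- 0
  p$interval_jitter_sd <- 0
  p$symptom_onset_hazard <- onset
  p$growth <- growth
  p
}

harness_truth <- function(agents) {
  truth <- claims_fixture("tokyo")
  truth$base_total_patients <-
    sum(agents$weight[agents$state == "diagnosed_continuous_care"])
  truth
}

# exact LP oracle: enumerate basic feasible solutions of the standard-form
# localization program (weights + split L1 deviations, equality constraints)
localize_bruteforce <- function(cells, sex_targets, cond_targets, total) {
  k <- nrow(cells)
  A_marg <- rbind(
    as.numeric(cells$sex == "male"),
    as.numeric(cells$sex == "female"),
    as.numeric(cells$condition == "UC"),
    as.numeric(cells$condition == "CD")
  )
  m <- 4
  Aeq <- rbind(cbind(A_marg, -diag(m), diag(m)),
               c(rep(1, k), rep(0, 2 * m)))
  beq <- c(sex_targets[["male"]], sex_targets[["female"]],
           cond_targets[["UC"]], cond_targets[["CD"]], total)
  cc <- c(rep(0, k), rep(1, 2 * m))
  nv <- ncol(Aeq)
  best <- Inf
  for (basis in utils::combn(nv, nrow(Aeq), simplify = FALSE)) {
    B <- Aeq[, basis, drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    x <- rep(0, nv)
    xb <- solve(B, beq)
    if (any(xb < -1e-9)) next
    x[basis] <- pmax(xb, 0)
    best <- min(best, sum(cc * x))
  }
  best
}
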