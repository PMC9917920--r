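#' Clinical-pathway parameters
#'
#' Weekly-timestep parameters of the IBD patient pathway. All hazards are
#' per-week probabilities; intervals are in weeks. Annual probabilities can
#' be converted with [annual_to_weekly()].
#'
#' @param symptom_onset_hazard per-week probability that an undiagnosed
#'   asymptomatic agent develops symptoms, at week 0 (the incidence process
#'   grows geometrically with `growth`).
#' @param growth yearly growth factor g of the incidence process; the
#'   effective hazard at week w is `symptom_onset_hazard * g^(w/52)`.
#' @param care_seeking_hazard per-week probability that a symptomatic agent
#'   attempts a new-patient visit.
#' @param diagnosis_probability probability that a completed new-patient
#'   visit with a diagnostic procedure yields a diagnosis.
#' @param visit_interval named numeric, weeks between continuous-care visits
#'   per severity (`mild_moderate`, `moderate_severe`).
#' @param procedure_interval named numeric, weeks between monitoring
#'   procedures per severity.
#' @param biologic_interval weeks between biologic dispensings (vedolizumab
#'   maintenance is every 8 weeks).
#' @param biologic_initiation_hazard per-week probability that a
#'   moderate-to-severe agent on conventional therapy starts a biologic.
#' @param severity_progression_hazard per-week probability of
#'   mild-to-moderate -> moderate-to-severe progression.
#' @param interval_jitter_sd SD (weeks) of the normal jitter added to each
#'   scheduled interval (rounded, floored at 1 week); prevents artificial
#'   synchronization of visit cycles.
#' @return an object of class `pathway_parameters` (a validated list).
#' @export
pathway_parameters <- function(symptom_onset_hazard,
                               growth = 1,
                               care_seeking_hazard,
                               diagnosis_probability,
                               visit_interval,
                               procedure_interval,
                               biologic_interval,
                               biologic_initiation_hazard,
                               severity_progression_hazard,
                               interval_jitter_sd = 0) {
  p <- list(symptom_onset_hazard = symptom_onset_hazard,
            growth = growth,
            care_seeking_hazard = care_seeking_hazard,
            diagnosis_probability = diagnosis_probability,
            visit_interval = visit_interval,
            procedure_interval = procedure_interval,
            biologic_interval = biologic_interval,
            biologic_initiation_hazard = biologic_initiation_hazard,
            severity_progression_hazard = severity_progression_hazard,
            interval_jitter_sd = interval_jitter_sd)
  for (nm in c("symptom_onset_hazard", "care_seeking_hazard",
               "diagnosis_probability", "biologic_initiation_hazard",
               "severity_progression_hazard")) {
    v <- p[[nm]]
    if (length(v) != 1 || v < 0 || v > 1) {
      stop(sprintf("%s must be a probability in [0,1]", nm), call. = FALSE)
    }
  }
  if (p$growth <= 0) stop("growth must be > 0", call. = FALSE)
  for (nm in c("visit_interval", "procedure_interval")) {
    v <- p[[nm]]
    if (!all(c("mild_moderate", "moderate_severe") %in% names(v))) {
      stop(sprintf("%s needs entries mild_moderate and moderate_severe", nm),
           call. = FALSE)
    }
    if (any(v < 1)) stop(sprintf("%s must be >= 1 week", nm), call. = FALSE)
  }
  if (p$biologic_interval < 1) {
    stop("biologic_interval must be >= 1 week", call. = FALSE)
  }
  if (p$interval_jitter_sd < 0) {
    stop("interval_jitter_sd must be >= 0", call. = FALSE)
  }
  class(p) <- "pathway_parameters"
  p
}

#' Convert an annual probability to the equivalent per-week probability
#'
#' @param p_annual annual probability in `[0, 1]`.
#' @return `1 - (1 - p_annual)^(1/52)`.
#' @export
annual_to_weekly <- function(p_annual) 1 - (1 - p_annual)^(1 / 52)

#' Default pathway parameters
#'
#' Shipped defaults chosen so that baseline per-capita utilization is of a
#' realistic order for maintenance IBD care (mild patients review roughly
#' every 8 weeks, severe every 4; colonoscopic/biomarker monitoring every
#' 26/13 weeks; biologic maintenance every 8 weeks). They are calibration
#' starting points, not published facts.
#'
#' @return a [pathway_parameters()] object.
#' @export
default_pathway_parameters <- function() {
  pathway_parameters(
    symptom_onset_hazard = 2e-4,
    growth = 1.08,
    care_seeking_hazard = 0.30,
    diagnosis_probability = 0.80,
    visit_interval = c(mild_moderate = 8, moderate_severe = 4),
    procedure_interval = c(mild_moderate = 26, moderate_severe = 13),
    biologic_interval = 8,
    biologic_initiation_hazard = 0.005,
    severity_progression_hazard = 0.002,
    interval_jitter_sd = 1
  )
}

#' Read / write pathway parameters as JSON
#' @param path JSON file path.
#' @return a [pathway_parameters()] object.
#' @export
read_pathway_config <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  pathway_parameters(
    symptom_onset_hazard = cfg$symptom_onset_hazard,
    growth = cfg$growth,
    care_seeking_hazard = cfg$care_seeking_hazard,
    diagnosis_probability = cfg$diagnosis_probability,
    visit_interval = unlist(cfg$visit_interval),
    procedure_interval = unlist(cfg$procedure_interval),
    biologic_interval = cfg$biologic_interval,
    biologic_initiation_hazard = cfg$biologic_initiation_hazard,
    severity_progression_hazard = cfg$severity_progression_hazard,
    interval_jitter_sd = cfg$interval_jitter_sd
  )
}

#' Effective symptom-onset hazard at a given week
#'
#' The incidence process grows geometrically: the effective hazard at week
#' `w` is the base hazard times `g^(w/52)`, nondecreasing in `w` for
#' `g >= 1`.
#'
#' @param params a [pathway_parameters()] object.
#' @param week 0-based week index (vectorized).
#' @return effective per-week onset hazard.
#' @export
advance_incidence <- function(params, week) {
  if (any(week < 0)) stop("week must be >= 0", call. = FALSE)
  params$symptom_onset_hazard * params$growth^(week / 52)
}

#' Single-agent weekly transition (reference semantics)
#'
#' Advances one agent's pathway state by one week and reports the weighted
#' event contributions. This is the reference single-agent form of the
#' update rule the simulation engine applies to whole populations; demand
#' multipliers scale attendance (care seeking, scheduled visits, refills)
#' while biology (symptom onset, severity progression) is never scaled.
#' Attendance failures are reported as deferred events. Service capacity is
#' not modelled at single-agent scale; see [run_simulation()] for the
#' population form with capacity and backlog.
#'
#' @param state one-row data.frame (or list) with the agent state columns of
#'   [generate_population()].
#' @param params a [pathway_parameters()] object.
#' @param demand_multiplier named numeric with `care_seeking`,
#'   `continuous_care_visits`, `biologic_refill` in `[0, Inf)`.
#' @param week 0-based week index.
#' @return list with `state` (updated one-row state) and `events` (named
#'   weighted counts: `new_patients`, `outpatient_visits`, `procedures`,
#'   `biologics`, `new_biologic_starts`, `deferred_care_seeking`,
#'   `deferred_visits`, `deferred_procedures`, `deferred_biologic`).
#' @export
step_agent <- function(state, params,
                       demand_multiplier = c(care_seeking = 1,
                                             continuous_care_visits = 1,
                                             biologic_refill = 1),
                       week = 0) {
  s <- as.list(state)
  w <- s$weight
  ev <- c(new_patients = 0, outpatient_visits = 0, procedures = 0,
          biologics = 0, new_biologic_starts = 0,
          deferred_care_seeking = 0, deferred_visits = 0,
          deferred_procedures = 0, deferred_biologic = 0)
  jitter <- function(base) {
    if (params$interval_jitter_sd > 0) {
      base <- base + stats::rnorm(1, 0, params$interval_jitter_sd)
    }
    max(1, round(base))
  }
  sev_key <- function() {
    if (s$severity == "moderate_severe") "moderate_severe" else "mild_moderate"
  }

  if (s$state == "undiagnosed_asymptomatic") {
    if (stats::runif(1) < advance_incidence(params, week)) {
      s$state <- "symptomatic_seeking_care"
      s$weeks_since_onset <- 0
    }
  }
  if (s$state == "symptomatic_seeking_care") {
    if (stats::runif(1) < params$care_seeking_hazard * s$propensity) {
      if (stats::runif(1) < demand_multiplier[["care_seeking"]]) {
        ev["outpatient_visits"] <- w
        ev["procedures"] <- w
        if (stats::runif(1) < params$diagnosis_probability) {
          s$state <- "diagnosed_continuous_care"
          s$treatment <- "conventional"
          ev["new_patients"] <- w
          s$next_visit_due <- week + jitter(params$visit_interval[[sev_key()]])
          s$weeks_since_procedure <- 0
          s$procedure_threshold <- jitter(params$procedure_interval[[sev_key()]])
        }
      } else {
        ev["deferred_care_seeking"] <- w
      }
    }
    if (s$state == "symptomatic_seeking_care") {
      s$weeks_since_onset <- s$weeks_since_onset + 1
    }
  } else if (s$state == "diagnosed_continuous_care") {
    if (s$severity == "mild_moderate" &&
        stats::runif(1) < params$severity_progression_hazard) {
      s$severity <- "moderate_severe"
    }
    if (s$severity == "moderate_severe" && s$treatment == "conventional" &&
        stats::runif(1) < params$biologic_initiation_hazard) {
      s$treatment <- "biologic"
      s$weeks_since_biologic <- params$biologic_interval
      s$biologic_threshold <- params$biologic_interval
    }
    if (!is.na(s$next_visit_due) && week >= s$next_visit_due) {
      if (stats::runif(1) < demand_multiplier[["continuous_care_visits"]]) {
        ev["outpatient_visits"] <- ev[["outpatient_visits"]] + w
        s$next_visit_due <- week + jitter(params$visit_interval[[sev_key()]])
      } else {
        # skipped, not retried: wait for the next regular visit
        ev["deferred_visits"] <- w
        s$next_visit_due <- week + jitter(params$visit_interval[[sev_key()]])
      }
    }
    if (!is.na(s$weeks_since_procedure) &&
        s$weeks_since_procedure >= s$procedure_threshold) {
      if (stats::runif(1) < demand_multiplier[["continuous_care_visits"]]) {
        ev["procedures"] <- ev[["procedures"]] + w
        s$weeks_since_procedure <- 0
        s$procedure_threshold <- jitter(params$procedure_interval[[sev_key()]])
      } else {
        ev["deferred_procedures"] <- w
        s$weeks_since_procedure <- 0
        s$procedure_threshold <- jitter(params$procedure_interval[[sev_key()]])
      }
    }
    if (s$treatment == "biologic" && !is.na(s$weeks_since_biologic) &&
        s$weeks_since_biologic >= s$biologic_threshold) {
      if (stats::runif(1) < demand_multiplier[["biologic_refill"]]) {
        ev["biologics"] <- w
        if (!isTRUE(as.logical(s$ever_biologic))) {
          ev["new_biologic_starts"] <- w
          s$ever_biologic <- TRUE
        }
        s$weeks_since_biologic <- 0
        s$biologic_threshold <- jitter(params$biologic_interval)
      } else {
        ev["deferred_biologic"] <- w
      }
    }
    if (!is.na(s$weeks_since_procedure)) {
      s$weeks_since_procedure <- s$weeks_since_procedure + 1
    }
    if (s$treatment == "biologic" && !is.na(s$weeks_since_biologic)) {
      s$weeks_since_biologic <- s$weeks_since_biologic + 1
    }
  }
  list(state = as.data.frame(s, stringsAsFactors = FALSE), events = ev)
}
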