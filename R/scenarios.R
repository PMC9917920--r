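#' Scenario modifier series
#'
#' Per-week multipliers applied to the simulation: demand multipliers scale
#' attendance probabilities (new-patient care seeking, continuous-care
#' visits including monitoring procedures, biologic refills) and supply
#' multipliers scale service capacity (outpatient visits, procedures,
#' biologic dispensing). A value of 1 is no disruption; 0 suppresses the
#' channel completely.
#'
#' @param horizon number of weeks.
#' @param d_care_seeking,d_continuous,d_biologic demand multipliers
#'   (recycled to `horizon`).
#' @param s_outpatient,s_procedures,s_biologic supply multipliers.
#' @return data.frame of class `scenario_modifiers` with a `week` column
#'   (0-based) and the six multiplier columns.
#' @export
scenario_modifiers <- function(horizon, d_care_seeking = 1, d_continuous = 1,
                               d_biologic = 1, s_outpatient = 1,
                               s_procedures = 1, s_biologic = 1) {
  stopifnot(horizon >= 1)
  df <- data.frame(
    week = seq_len(horizon) - 1L,
    d_care_seeking = rep_len(d_care_seeking, horizon),
    d_continuous = rep_len(d_continuous, horizon),
    d_biologic = rep_len(d_biologic, horizon),
    s_outpatient = rep_len(s_outpatient, horizon),
    s_procedures = rep_len(s_procedures, horizon),
    s_biologic = rep_len(s_biologic, horizon)
  )
  if (any(as.matrix(df[, -1]) < 0)) {
    stop("scenario multipliers must be >= 0", call. = FALSE)
  }
  class(df) <- c("scenario_modifiers", "data.frame")
  df
}

#' @rdname scenario_modifiers
#' @export
identity_scenario <- function(horizon) scenario_modifiers(horizon)

#' Pandemic behavioral-response parameters
#'
#' Parameters of the reconstructed wave-response function used to translate
#' an exogenous weekly COVID-case series into disruption multipliers. The
#' functional form (case-count saturation, an additive boost while a state
#' of emergency is declared, and exponential habituation of the response
#' with continued exposure) encodes the qualitative record: the first,
#' smallest wave — accompanied by an emergency declaration — caused the
#' largest disruption, and later larger waves progressively less.
#'
#' @param case_saturation weekly case count at half-maximal impact.
#' @param max_demand_impact peak fractional demand reduction (A_d).
#' @param max_supply_impact peak fractional supply reduction (A_s).
#' @param emergency_boost additive impact while an emergency is declared.
#' @param adaptation_halflife weeks of exposure that halve the response.
#' @return object of class `pandemic_response_params`.
#' @export
pandemic_response_params <- function(case_saturation = 2000,
                                     max_demand_impact = 0.4,
                                     max_supply_impact = 0.3,
                                     emergency_boost = 0.2,
                                     adaptation_halflife = 26) {
  stopifnot(case_saturation > 0,
            max_demand_impact >= 0, max_demand_impact <= 1,
            max_supply_impact >= 0, max_supply_impact <= 1,
            emergency_boost >= 0, emergency_boost <= 1,
            adaptation_halflife > 0)
  structure(list(case_saturation = case_saturation,
                 max_demand_impact = max_demand_impact,
                 max_supply_impact = max_supply_impact,
                 emergency_boost = emergency_boost,
                 adaptation_halflife = adaptation_halflife),
            class = "pandemic_response_params")
}

#' Build pandemic scenario modifiers from a COVID-wave series
#'
#' The raw impact at week t is
#' `A * c(t) / (c(t) + case_saturation) + emergency_boost * 1[emergency]`,
#' damped by habituation `2^(-E(t) / adaptation_halflife)` where `E(t)` is
#' the number of weeks elapsed since the impact first became nonzero (the
#' habituation clock starts at first exposure and keeps running). The
#' multiplier is `1 - impact`, clipped to `[0, 1]`; demand channels use
#' `max_demand_impact` and supply channels `max_supply_impact`. Two waves of
#' equal case counts therefore produce a strictly smaller peak impact the
#' second time.
#'
#' @param waves data.frame with columns `week_start` (Date), `new_cases`
#'   (nonnegative), `emergency_declared` (logical or 0/1); contiguous weeks.
#' @param params a [pandemic_response_params()].
#' @return a [scenario_modifiers()] covering the wave series.
#' @export
build_pandemic_scenario <- function(waves, params) {
  stopifnot(inherits(params, "pandemic_response_params"))
  if (is.null(waves) || nrow(waves) == 0) {
    stop("wave series is empty", call. = FALSE)
  }
  if (any(waves$new_cases < 0)) {
    stop("new_cases must be >= 0", call. = FALSE)
  }
  n <- nrow(waves)
  cases <- as.numeric(waves$new_cases)
  emerg <- as.logical(waves$emergency_declared)
  sat <- cases / (cases + params$case_saturation)
  raw_d <- params$max_demand_impact * sat +
    params$emergency_boost * as.numeric(emerg)
  raw_s <- params$max_supply_impact * sat +
    params$emergency_boost * as.numeric(emerg)
  nonzero <- raw_d > 0 | raw_s > 0
  first <- if (any(nonzero)) which(nonzero)[1] else NA_integer_
  expo <- numeric(n)
  if (!is.na(first)) {
    expo[first:n] <- seq_len(n - first + 1) - 1
  }
  damp <- 2^(-expo / params$adaptation_halflife)
  imp_d <- pmin(pmax(raw_d * damp, 0), 1)
  imp_s <- pmin(pmax(raw_s * damp, 0), 1)
  mod <- scenario_modifiers(
    n,
    d_care_seeking = 1 - imp_d, d_continuous = 1 - imp_d,
    d_biologic = 1 - imp_d,
    s_outpatient = 1 - imp_s, s_procedures = 1 - imp_s,
    s_biologic = 1 - imp_s
  )
  attr(mod, "week_start") <- as.Date(waves$week_start)
  mod
}

#' Earthquake scenario: immediate step drop with linear recovery
#'
#' Both demand and supply drop to `1 - severity` at `start_week` and return
#' linearly to 1 over `recovery_weeks`: the multiplier at `start_week + k`
#' is `1 - severity * (1 - k / recovery_weeks)` for `k = 0 ... recovery`.
#' The summed disruption (1 - multiplier over all weeks) has the closed form
#' `severity * (recovery_weeks + 1) / 2`.
#'
#' @param horizon total weeks covered.
#' @param start_week 0-based week of the shock.
#' @param severity fraction in `[0, 1]`.
#' @param recovery_weeks weeks of linear recovery, `>= 1`.
#' @return a [scenario_modifiers()].
#' @export
build_earthquake_scenario <- function(horizon, start_week, severity,
                                      recovery_weeks) {
  stopifnot(severity >= 0, severity <= 1, recovery_weeks >= 1)
  deficit <- numeric(horizon)
  for (k in 0:recovery_weeks) {
    w <- start_week + k
    if (w >= 0 && w < horizon) {
      deficit[w + 1] <- severity * (1 - k / recovery_weeks)
    }
  }
  m <- pmin(pmax(1 - deficit, 0), 1)
  scenario_modifiers(horizon, d_care_seeking = m, d_continuous = m,
                     d_biologic = m, s_outpatient = m, s_procedures = m,
                     s_biologic = m)
}

#' Financial-crisis scenario: prolonged demand-side disruption
#'
#' Purely a demand-side disruption: supply multipliers stay at 1
#' throughout. Demand drops to `1 - depth` at `start_week` (the single ramp
#' week), holds for `duration_weeks`, then returns linearly to 1 over
#' `recovery_weeks`.
#'
#' @param horizon total weeks covered.
#' @param start_week 0-based week the crisis begins.
#' @param depth fraction in `[0, 1]`.
#' @param duration_weeks weeks held at full depth after the ramp week.
#' @param recovery_weeks weeks of linear recovery.
#' @return a [scenario_modifiers()] whose supply columns are identically 1.
#' @export
build_financial_crisis_scenario <- function(horizon, start_week, depth,
                                            duration_weeks, recovery_weeks) {
  stopifnot(depth >= 0, depth <= 1, duration_weeks >= 0, recovery_weeks >= 0)
  deficit <- numeric(horizon)
  for (k in 0:duration_weeks) {
    w <- start_week + k
    if (w >= 0 && w < horizon) deficit[w + 1] <- depth
  }
  if (recovery_weeks > 0) {
    for (k in seq_len(recovery_weeks)) {
      w <- start_week + duration_weeks + k
      if (w >= 0 && w < horizon) {
        deficit[w + 1] <- depth * (1 - k / (recovery_weeks + 1))
      }
    }
  }
  m <- pmin(pmax(1 - deficit, 0), 1)
  scenario_modifiers(horizon, d_care_seeking = m, d_continuous = m,
                     d_biologic = m, s_outpatient = 1, s_procedures = 1,
                     s_biologic = 1)
}

#' Synthetic two-wave COVID case series
#'
#' A 44-week weekly series (January to October 2020) with a small first
#' wave accompanied by an emergency declaration and a larger second wave
#' without one — the qualitative structure of the observed record in which
#' the first, smaller wave caused the largest behavioral disruption. Used
#' by the calibration harness and as a packaged example input; it is a
#' synthetic stand-in, not surveillance data.
#'
#' @param start_date Monday of week 0.
#' @return data.frame with `week_start`, `new_cases`, `emergency_declared`.
#' @export
synthetic_wave_series <- function(start_date = as.Date("2020-01-06")) {
  n <- 44
  w <- 0:(n - 1)
  cases <- round(1500 * exp(-((w - 12)^2) / (2 * 2.5^2)) +
                 4000 * exp(-((w - 29)^2) / (2 * 3.5^2)))
  cases[cases < 5] <- 0
  emergency <- w >= 13 & w <= 19
  data.frame(week_start = start_date + 7 * w,
             new_cases = as.numeric(cases),
             emergency_declared = emergency)
}

#' Read a weekly COVID-wave input series
#'
#' @param path CSV with header `week_start,new_cases,emergency_declared`.
#' @return data.frame with parsed dates, nonnegative case counts, and a
#'   logical emergency flag; weeks must be contiguous.
#' @export
read_covid_waves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("week_start", "new_cases", "emergency_declared")
  if (!all(need %in% names(df))) {
    stop("wave CSV must have header: ", paste(need, collapse = ","),
         call. = FALSE)
  }
  df$week_start <- as.Date(df$week_start)
  df$emergency_declared <- as.logical(df$emergency_declared)
  if (any(df$new_cases < 0)) stop("new_cases must be >= 0", call. = FALSE)
  if (nrow(df) > 1 && any(diff(df$week_start) != 7)) {
    stop("wave weeks must be contiguous", call. = FALSE)
  }
  df[, need]
}
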