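#' Construct a demand series
#'
#' A demand series is the weekly output contract of the simulator and the
#' input contract of calibration: one row per week, with the five historical
#' demand channels plus the two biologic-agent metrics.
#'
#' @param week_start vector of Dates (Mondays), contiguous weeks.
#' @param ... numeric columns `new_patients`, `total_patients`,
#'   `outpatient_visits`, `procedures`, `biologics`,
#'   `vedolizumab_infusions`, `new_vedolizumab_starts`.
#' @param region optional region label attached as an attribute.
#' @return data.frame of class `demand_series`.
#' @export
demand_series <- function(week_start, ..., region = NULL) {
  cols <- list(...)
  need <- series_channels()
  if (!all(need %in% names(cols))) {
    stop("demand_series needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- data.frame(week_start = as.Date(week_start), cols[need])
  if (any(unlist(cols[need]) < 0, na.rm = TRUE)) {
    stop("demand series counts must be >= 0", call. = FALSE)
  }
  if (nrow(df) > 1 && any(diff(df$week_start) != 7)) {
    stop("weeks must be contiguous (7-day spacing)", call. = FALSE)
  }
  attr(df, "region") <- region
  class(df) <- c("demand_series", "data.frame")
  df
}

series_channels <- function() {
  c("new_patients", "total_patients", "outpatient_visits", "procedures",
    "biologics", "vedolizumab_infusions", "new_vedolizumab_starts")
}

state_to_codes <- function(agents) {
  list(
    stage = match(agents$state, c("undiagnosed_asymptomatic",
                                  "symptomatic_seeking_care",
                                  "diagnosed_continuous_care")) - 1L,
    severity = match(agents$severity,
                     c("mild_moderate", "moderate_severe")) - 1L,
    treatment = match(agents$treatment,
                      c("none", "conventional", "biologic")) - 1L
  )
}

int_or <- function(x, default) {
  out <- ifelse(is.na(x), default, x)
  as.integer(round(out))
}

#' Run the demand simulation
#'
#' Steps every agent weekly through the clinical pathway under the given
#' scenario modifiers and capacity model, and aggregates weighted weekly
#' event tallies. Identical inputs and seed give an identical series.
#'
#' @param agents an `agent_population` from [generate_population()] (or a
#'   compatible data.frame).
#' @param params a [pathway_parameters()] object.
#' @param modifiers a `scenario_modifiers` object covering at least
#'   `horizon` weeks, or `NULL` for the identity (baseline) scenario.
#' @param capacity a [capacity_model()], or `NULL` for unconstrained supply.
#' @param horizon number of weeks to simulate (default 156 = 3 years).
#' @param seed integer seed.
#' @param start_date calendar date of week 0 (a Monday).
#' @param week_offset 0-based absolute index of the first simulated week
#'   (nonzero when continuing a run from a snapshot; the incidence growth
#'   clock uses absolute weeks).
#' @param initial_state optional engine state snapshot (as returned in the
#'   `state` attribute of a previous run) to continue from.
#' @param return_state if `TRUE`, attach the final engine state as attribute
#'   `state` for later continuation.
#' @return a [demand_series()] with attribute `diagnostics` (deferred
#'   events, backlog, and cumulative demanded/served/abandoned per service).
#' @export
run_simulation <- function(agents, params, modifiers = NULL, capacity = NULL,
                           horizon = 156L, seed,
                           start_date = as.Date("2015-01-05"),
                           week_offset = 0L, initial_state = NULL,
                           return_state = FALSE) {
  stopifnot(inherits(params, "pathway_parameters"), horizon >= 1)
  if (is.null(modifiers)) modifiers <- identity_scenario(horizon)
  mod <- as.data.frame(modifiers)
  if (nrow(mod) < horizon) {
    stop(sprintf("modifier series covers %d weeks but horizon is %d",
                 nrow(mod), horizon), call. = FALSE)
  }
  mod <- mod[seq_len(horizon), ]
  if (is.null(capacity)) capacity <- capacity_model()

  n <- nrow(agents)
  empty <- n == 0
  set.seed(as.integer(seed))

  if (empty) {
    z <- numeric(horizon)
    ws <- start_date + 7 * (seq_len(horizon) - 1)
    out <- demand_series(ws, new_patients = z, total_patients = z,
                         outpatient_visits = z, procedures = z, biologics = z,
                         vedolizumab_infusions = z, new_vedolizumab_starts = z,
                         region = attr(agents, "region"))
    return(out)
  }

  if (is.null(initial_state)) {
    codes <- state_to_codes(agents)
    evb <- agents$ever_biologic
    if (is.null(evb)) evb <- rep(FALSE, n)
    st <- list(
      stage = codes$stage, severity = codes$severity,
      treatment = codes$treatment,
      ever_biologic = as.integer(evb),
      pending_diag = integer(n),
      next_visit_due = int_or(agents$next_visit_due, 2e9),
      weeks_since_proc = int_or(agents$weeks_since_procedure, 0),
      thr_proc = int_or(agents$procedure_threshold, 1e9),
      weeks_since_bio = int_or(agents$weeks_since_biologic, 0),
      thr_bio = int_or(agents$biologic_threshold, 1e9)
    )
    undiag_w0 <- 0
    backlog0 <- c(0, 0, 0)
  } else {
    st <- initial_state$engine
    undiag_w0 <- initial_state$undiagnosed_weight0
    backlog0 <- initial_state$backlog
  }

  res <- .sim_core(
    st$stage, st$severity, st$treatment, agents$weight, agents$propensity,
    st$ever_biologic, st$pending_diag, st$next_visit_due,
    st$weeks_since_proc, st$thr_proc, st$weeks_since_bio, st$thr_bio,
    list(symptom_onset_hazard = params$symptom_onset_hazard,
         growth = params$growth,
         care_seeking_hazard = params$care_seeking_hazard,
         diagnosis_probability = params$diagnosis_probability,
         visit_interval = as.numeric(params$visit_interval[
           c("mild_moderate", "moderate_severe")]),
         procedure_interval = as.numeric(params$procedure_interval[
           c("mild_moderate", "moderate_severe")]),
         biologic_interval = params$biologic_interval,
         biologic_initiation_hazard = params$biologic_initiation_hazard,
         severity_progression_hazard = params$severity_progression_hazard,
         interval_jitter_sd = params$interval_jitter_sd),
    as.matrix(mod[, c("d_care_seeking", "d_continuous", "d_biologic")]),
    as.matrix(mod[, c("s_outpatient", "s_procedures", "s_biologic")]),
    as.numeric(capacity$weekly_capacity),
    capacity$backlog_service_rate, capacity$abandonment_rate,
    as.integer(horizon), as.integer(week_offset),
    undiag_w0, as.numeric(backlog0)
  )

  tally <- res$tally
  ws <- start_date + 7 * (seq_len(horizon) - 1)
  out <- demand_series(
    ws,
    new_patients = tally[, 1], total_patients = tally[, 2],
    outpatient_visits = tally[, 3], procedures = tally[, 4],
    biologics = tally[, 5], vedolizumab_infusions = tally[, 6],
    new_vedolizumab_starts = tally[, 7],
    region = agents$region[1]
  )
  diag_cols <- c("deferred_care_seeking", "deferred_visits",
                 "deferred_procedures", "deferred_biologic",
                 "backlog_outpatient", "backlog_procedures", "backlog_biologic",
                 "cum_demanded_outpatient", "cum_demanded_procedures",
                 "cum_demanded_biologic", "cum_served_outpatient",
                 "cum_served_procedures", "cum_served_biologic",
                 "cum_abandoned_outpatient", "cum_abandoned_procedures",
                 "cum_abandoned_biologic")
  diagnostics <- as.data.frame(tally[, 8:23, drop = FALSE])
  names(diagnostics) <- diag_cols
  diagnostics$week_start <- ws
  attr(out, "diagnostics") <- diagnostics
  attr(out, "seed") <- as.integer(seed)
  if (return_state) {
    attr(out, "state") <- list(engine = res$state,
                               undiagnosed_weight0 = res$undiagnosed_weight0,
                               backlog = res$backlog)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a seeded ensemble and summarize it
#'
#' Runs `n_runs` replicates with seeds `base_seed + 0 ... n_runs - 1` and
#' returns per-week five-number summaries (minimum, Q1, median, Q3, maximum)
#' of every channel, the box-and-whisker statistics used to display weekly
#' ensembles.
#'
#' @param run_spec list of arguments for [run_simulation()] (everything but
#'   `seed`): `agents`, `params`, and optionally `modifiers`, `capacity`,
#'   `horizon`, `start_date`.
#' @param n_runs number of replicate runs (published displays use 50).
#' @param base_seed integer; replicate r uses seed `base_seed + r - 1`.
#' @return data.frame of class `ensemble_summary` with columns `channel`,
#'   `week_start`, `min`, `q1`, `median`, `q3`, `max`; attribute `n_runs`.
#' @export
run_ensemble <- function(run_spec, n_runs, base_seed) {
  stopifnot(n_runs >= 1)
  runs <- lapply(seq_len(n_runs) - 1L, function(r) {
    do.call(run_simulation, c(run_spec, list(seed = base_seed + r)))
  })
  channels <- series_channels()
  ws <- runs[[1]]$week_start
  pieces <- lapply(channels, function(ch) {
    mat <- vapply(runs, function(s) s[[ch]], numeric(length(ws)))
    mat <- matrix(mat, nrow = length(ws))
    qs <- t(apply(mat, 1, stats::quantile,
                  probs = c(0, 0.25, 0.5, 0.75, 1), names = FALSE))
    data.frame(channel = ch, week_start = ws, min = qs[, 1], q1 = qs[, 2],
               median = qs[, 3], q3 = qs[, 4], max = qs[, 5],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  attr(out, "n_runs") <- n_runs
  attr(out, "base_seed") <- base_seed
  class(out) <- c("ensemble_summary", "data.frame")
  out
}

#' Average a weekly series by calendar month
#'
#' Weeks are assigned to the calendar month of their start date; each
#' month's value is the mean of its weekly values.
#'
#' @param series a [demand_series()] (or any data.frame with `week_start`
#'   and numeric columns).
#' @return data.frame with `month` (first of month, Date) and the monthly
#'   mean of each numeric column.
#' @export
aggregate_monthly <- function(series) {
  df <- as.data.frame(series)
  if (!"week_start" %in% names(df)) {
    stop("series must carry a week_start date column", call. = FALSE)
  }
  month <- as.Date(format(df$week_start, "%Y-%m-01"))
  num_cols <- names(df)[vapply(df, is.numeric, logical(1))]
  agg <- stats::aggregate(df[num_cols], by = list(month = month), FUN = mean)
  agg[order(agg$month), , drop = FALSE]
}
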