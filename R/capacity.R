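#' Service capacity and backlog model
#'
#' Weekly service capacity per service (outpatient visits, procedures,
#' biologic dispensing), with an aggregate backlog queue. Demanded volume in
#' excess of effective capacity (capacity times the week's supply
#' multiplier) carries forward as backlog; during recovery a fraction
#' `backlog_service_rate` of the backlog is admitted each week and a
#' fraction `abandonment_rate` of what remains is dropped. Rapid backlog
#' alleviation (a high service rate) after a deep disruption produces
#' post-recovery oscillations in served volume because the natural
#' periodicity of visit schedules bunches the released demand.
#'
#' @param weekly_capacity named numeric `c(outpatient_visits = ,
#'   procedures = , biologic_dispensing = )`; `Inf` disables the constraint.
#' @param backlog_service_rate fraction of backlog admitted per week.
#' @param abandonment_rate fraction of remaining backlog dropped per week.
#' @return an object of class `capacity_model`.
#' @export
capacity_model <- function(weekly_capacity = c(outpatient_visits = Inf,
                                               procedures = Inf,
                                               biologic_dispensing = Inf),
                           backlog_service_rate = 0.2,
                           abandonment_rate = 0) {
  need <- c("outpatient_visits", "procedures", "biologic_dispensing")
  if (!all(need %in% names(weekly_capacity))) {
    stop("weekly_capacity must name outpatient_visits, procedures, ",
         "biologic_dispensing", call. = FALSE)
  }
  wc <- weekly_capacity[need]
  stopifnot(all(wc >= 0),
            backlog_service_rate >= 0, backlog_service_rate <= 1,
            abandonment_rate >= 0, abandonment_rate <= 1)
  structure(list(weekly_capacity = wc,
                 backlog_service_rate = backlog_service_rate,
                 abandonment_rate = abandonment_rate,
                 backlog = c(outpatient_visits = 0, procedures = 0,
                             biologic_dispensing = 0)),
            class = "capacity_model")
}

#' Pass demanded service volume through capacity for one week
#'
#' Aggregate arithmetic of the capacity/backlog model: admitted backlog is
#' `backlog * backlog_service_rate`; served volume is
#' `min(demanded + admitted, capacity * supply_multiplier)` (allocated
#' proportionally between fresh demand and admitted backlog); unserved
#' demand and unadmitted backlog carry forward, minus abandonment. The
#' conservation identity
#' `cumulative demanded = cumulative served + backlog + cumulative abandoned`
#' holds exactly.
#'
#' @param demanded named nonnegative demand per service this week.
#' @param capacity a [capacity_model()] (carries the current backlog).
#' @param supply_multiplier named per-service fraction for this week
#'   (default all 1).
#' @return list with `served` (named, includes late-delivered backlog),
#'   `capacity` (updated model with new backlog), and `abandoned` (named).
#' @export
apply_capacity <- function(demanded, capacity,
                           supply_multiplier = c(outpatient_visits = 1,
                                                 procedures = 1,
                                                 biologic_dispensing = 1)) {
  stopifnot(inherits(capacity, "capacity_model"))
  need <- names(capacity$weekly_capacity)
  demanded <- demanded[need]
  if (any(is.na(demanded)) || any(demanded < 0)) {
    stop("demanded must be named nonnegative volume per service",
         call. = FALSE)
  }
  sm <- supply_multiplier[need]
  served <- abandoned <- stats::setNames(numeric(3), need)
  for (s in need) {
    admitted <- capacity$backlog[[s]] * capacity$backlog_service_rate
    cap <- capacity$weekly_capacity[[s]] * sm[[s]]
    if (is.infinite(capacity$weekly_capacity[[s]]) && sm[[s]] == 0) cap <- 0
    pool <- demanded[[s]] + admitted
    srv <- min(pool, cap)
    new_backlog <- capacity$backlog[[s]] - admitted + (pool - srv)
    ab <- new_backlog * capacity$abandonment_rate
    capacity$backlog[[s]] <- new_backlog - ab
    served[[s]] <- srv
    abandoned[[s]] <- ab
  }
  list(served = served, capacity = capacity, abandoned = abandoned)
}
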