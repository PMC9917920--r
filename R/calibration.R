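#' Calibration target: an observed series, a phase, and a date range
#'
#' @param region region label.
#' @param phase `"pre_covid"` (baseline growth and intervals) or `"covid"`
#'   (disruption response).
#' @param observed a [demand_series()] of observed (claims-derived or
#'   synthetic) weekly counts covering the range.
#' @param range length-2 Date vector; defaults to 2015-01-01..2019-12-31
#'   for `pre_covid` and 2020-01-01..2020-10-31 for `covid`.
#' @return object of class `calibration_target`.
#' @export
calibration_target <- function(region, phase = c("pre_covid", "covid"),
                               observed, range = NULL) {
  phase <- match.arg(phase)
  if (is.null(range)) {
    range <- if (phase == "pre_covid") {
      as.Date(c("2015-01-01", "2019-12-31"))
    } else {
      as.Date(c("2020-01-01", "2020-10-31"))
    }
  }
  structure(list(region = region, phase = phase, observed = observed,
                 range = as.Date(range)),
            class = "calibration_target")
}

#' Normalized monthly misfit between simulated and observed series
#'
#' Both series are aggregated to calendar-month means over their
#' overlapping range; each channel contributes the mean squared error of
#' `(simulated - observed) / mean(observed)` — normalization by the
#' observed channel mean makes channels of different magnitude comparable —
#' weighted by `channel_weights`. Channels with zero observed mean are
#' excluded with a warning; zero-weight channels are ignored.
#'
#' @param simulated,observed [demand_series()] objects with overlapping
#'   dates.
#' @param channel_weights named nonnegative weights over the series
#'   channels (missing channels get weight 0).
#' @param range optional Date range restricting the comparison.
#' @return nonnegative scalar objective.
#' @export
calibration_objective <- function(simulated, observed,
                                  channel_weights = c(new_patients = 1,
                                                      total_patients = 1,
                                                      outpatient_visits = 1,
                                                      procedures = 1,
                                                      biologics = 1),
                                  range = NULL) {
  sim <- as.data.frame(simulated)
  obs <- as.data.frame(observed)
  if (!is.null(range)) {
    sim <- sim[sim$week_start >= range[1] & sim$week_start <= range[2], ]
    obs <- obs[obs$week_start >= range[1] & obs$week_start <= range[2], ]
  }
  keep_sim <- sim$week_start %in% obs$week_start
  if (!any(keep_sim)) {
    stop("simulated and observed series do not overlap", call. = FALSE)
  }
  obs <- obs[obs$week_start %in% sim$week_start, ]
  sim <- sim[keep_sim, ]
  ms <- aggregate_monthly(sim)
  mo <- aggregate_monthly(obs)
  total <- 0
  for (ch in names(channel_weights)) {
    wgt <- channel_weights[[ch]]
    if (wgt == 0) next
    if (!ch %in% names(ms) || !ch %in% names(mo)) next
    mu <- mean(mo[[ch]])
    if (mu == 0) {
      warning(sprintf("channel %s has zero observed mean; excluded", ch),
              call. = FALSE)
      next
    }
    total <- total + wgt * mean(((ms[[ch]] - mo[[ch]]) / mu)^2)
  }
  total
}

# replace fitted fields in a pathway_parameters object; *_scale names
# multiply the default interval vectors
set_pathway_params <- function(params, theta) {
  for (nm in names(theta)) {
    v <- theta[[nm]]
    if (nm == "visit_interval_scale") {
      params$visit_interval <- pmax(1, round(params$visit_interval * v))
    } else if (nm == "procedure_interval_scale") {
      params$procedure_interval <- pmax(1, round(params$procedure_interval * v))
    } else if (nm %in% names(params)) {
      params[[nm]] <- v
    } else {
      stop(sprintf("unknown calibration parameter: %s", nm), call. = FALSE)
    }
  }
  params
}

# multi-start Nelder-Mead over a box, replicate-averaged objective with
# common random numbers; returns the best point found
box_search <- function(objective, bounds, seed, n_starts, maxit) {
  nm <- names(bounds)
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  k <- length(nm)
  n_eval <- 0L
  wrapped <- function(x) {
    n_eval <<- n_eval + 1L
    xc <- pmin(pmax(x, lo), hi)
    pen <- sum((x - xc)^2) * 1e4
    objective(stats::setNames(xc, nm)) + pen
  }
  if (all(hi - lo < 1e-12)) {
    val <- wrapped(lo)
    return(list(par = stats::setNames(lo, nm), value = val,
                n_evaluations = n_eval, starts = NULL))
  }
  set.seed(as.integer(seed))
  if (k == 1) {
    # grid scan plus local quadratic refinement: replicate-averaged
    # objectives carry Monte-Carlo jitter, so the vertex of a quadratic
    # fitted around the grid minimum is a more stable estimate than a
    # line search chasing individual evaluations
    grid <- seq(lo, hi, length.out = max(15, min(25, maxit)))
    vals <- vapply(grid, wrapped, numeric(1))
    i0 <- which.min(vals)
    win <- max(1, i0 - 4):min(length(grid), i0 + 4)
    qf <- stats::lm(vals[win] ~ grid[win] + I(grid[win]^2))
    cf <- stats::coef(qf)
    par <- if (is.na(cf[3]) || cf[3] <= 0) grid[i0] else -cf[2] / (2 * cf[3])
    par <- min(max(par, lo), hi)
    value <- wrapped(par)
    return(list(par = stats::setNames(par, nm), value = value,
                n_evaluations = n_eval,
                starts = data.frame(grid = grid, objective = vals)))
  }
  u <- lhs::randomLHS(n_starts, k)
  starts <- sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
  best <- NULL
  start_vals <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    x0 <- starts[s, ]
    fit <- stats::optim(x0, wrapped, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-5))
    start_vals[s] <- wrapped(x0)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(par = stats::setNames(pmin(pmax(best$par, lo), hi), nm),
       value = best$value, n_evaluations = n_eval,
       starts = data.frame(starts, objective = start_vals))
}

calibration_result <- function(par, objective_value, n_evaluations,
                               replicates, phase, diagnostics = list()) {
  structure(list(par = par, objective_value = objective_value,
                 n_evaluations = n_evaluations,
                 replicates_per_evaluation = replicates,
                 phase = phase, diagnostics = diagnostics),
            class = "calibration_result")
}

#' Fit baseline growth and utilization parameters (pre-COVID phase)
#'
#' Optimizes the named pathway parameters (typically the symptom-onset
#' hazard and the yearly growth factor g, optionally interval scales)
#' against the observed pre-COVID series: multi-start Nelder-Mead on a
#' bounded box, each evaluation averaging the normalized monthly misfit
#' over `replicates` stochastic runs with fixed replicate seeds (common
#' random numbers across evaluations).
#'
#' @param target a [calibration_target()] with phase `pre_covid`.
#' @param agents an `agent_population` used by every evaluation run.
#' @param params baseline [pathway_parameters()]; fields not being fitted
#'   are held at these values.
#' @param bounds named list of `c(lower, upper)` per fitted parameter;
#'   collapsed bounds (lower == upper) are returned as-is with their
#'   objective. Interval scales use names `visit_interval_scale`,
#'   `procedure_interval_scale`.
#' @param seed integer master seed (drives start placement and replicate
#'   seeds).
#' @param n_starts Latin-hypercube multi-starts (default 5).
#' @param replicates stochastic replicates averaged per evaluation
#'   (default 3).
#' @param maxit Nelder-Mead iteration cap per start.
#' @param channel_weights passed to [calibration_objective()].
#' @return a `calibration_result`.
#' @export
fit_baseline_growth <- function(target, agents, params, bounds, seed,
                                n_starts = 5, replicates = 3, maxit = 40,
                                channel_weights = c(new_patients = 1,
                                                    total_patients = 1)) {
  stopifnot(inherits(target, "calibration_target"),
            target$phase == "pre_covid")
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  if (any(hi < lo)) stop("infeasible bounds: upper < lower", call. = FALSE)
  obs <- target$observed
  sel <- obs$week_start >= target$range[1] & obs$week_start <= target$range[2]
  obs_win <- obs[sel, ]
  start_date <- obs_win$week_start[1]
  horizon <- nrow(obs_win)
  rep_seeds <- as.integer(seed) + 1000L + seq_len(replicates)

  objective <- function(theta) {
    p <- set_pathway_params(params, theta)
    vals <- vapply(rep_seeds, function(rs) {
      sim <- run_simulation(agents, p, horizon = horizon, seed = rs,
                            start_date = start_date)
      calibration_objective(sim, obs_win, channel_weights)
    }, numeric(1))
    mean(vals)
  }
  sol <- box_search(objective, bounds, seed, n_starts, maxit)
  calibration_result(sol$par, sol$value, sol$n_evaluations, replicates,
                     "pre_covid",
                     diagnostics = list(starts = sol$starts,
                                        channel_weights = channel_weights))
}

#' Fit the pandemic disruption-response parameters (COVID phase)
#'
#' Holds the baseline pathway parameters fixed, warms the population
#' through the pre-COVID period once per replicate (snapshots are reused
#' across evaluations), then fits the named wave-response parameters by the
#' same multi-start replicate-averaged search: each candidate builds
#' scenario modifiers from the wave series via [build_pandemic_scenario()]
#' and scores the simulated COVID window against the observed series.
#'
#' @param target a [calibration_target()] with phase `covid`; `observed`
#'   must cover the COVID window.
#' @param waves wave series (see [build_pandemic_scenario()]); its first
#'   week defines the start of the simulated COVID segment.
#' @param agents an `agent_population`.
#' @param params baseline-calibrated [pathway_parameters()].
#' @param template a [pandemic_response_params()] supplying the fields not
#'   being fitted.
#' @param bounds named list of `c(lower, upper)` over fields of the
#'   response (e.g. `max_demand_impact`, `adaptation_halflife`).
#' @param warmup_start date the warmup simulation begins (baseline phase
#'   start).
#' @param seed,n_starts,replicates,maxit as in [fit_baseline_growth()].
#' @param channel_weights passed to [calibration_objective()].
#' @return a `calibration_result`; `diagnostics$unidentifiable` flags
#'   `emergency_boost` when it is fitted but no emergency week exists.
#' @export
fit_disruption_response <- function(target, waves, agents, params, template,
                                    bounds, warmup_start =
                                      as.Date("2015-01-05"),
                                    seed, n_starts = 5, replicates = 3,
                                    maxit = 30,
                                    channel_weights = c(new_patients = 1,
                                                        outpatient_visits = 1,
                                                        procedures = 1,
                                                        biologics = 1)) {
  stopifnot(inherits(target, "calibration_target"), target$phase == "covid",
            inherits(template, "pandemic_response_params"))
  waves_start <- as.Date(waves$week_start[1])
  warmup_weeks <- as.integer((waves_start - as.Date(warmup_start)) / 7)
  if (warmup_weeks < 0) stop("waves start before warmup_start", call. = FALSE)
  horizon <- nrow(waves)
  rep_seeds <- as.integer(seed) + 2000L + seq_len(replicates)
  cov_seeds <- as.integer(seed) + 3000L + seq_len(replicates)

  snapshots <- lapply(rep_seeds, function(rs) {
    if (warmup_weeks == 0) return(NULL)
    sim <- run_simulation(agents, params, horizon = warmup_weeks, seed = rs,
                          start_date = warmup_start, return_state = TRUE)
    attr(sim, "state")
  })

  obs <- target$observed
  objective <- function(theta) {
    resp <- template
    for (nm in names(theta)) {
      if (!nm %in% names(resp)) {
        stop(sprintf("unknown response parameter: %s", nm), call. = FALSE)
      }
      resp[[nm]] <- theta[[nm]]
    }
    mod <- build_pandemic_scenario(waves, resp)
    vals <- vapply(seq_len(replicates), function(r) {
      sim <- run_simulation(agents, params, modifiers = mod,
                            horizon = horizon, seed = cov_seeds[r],
                            start_date = waves_start,
                            week_offset = warmup_weeks,
                            initial_state = snapshots[[r]])
      calibration_objective(sim, obs, channel_weights, range = target$range)
    }, numeric(1))
    mean(vals)
  }
  sol <- box_search(objective, bounds, seed, n_starts, maxit)
  diagnostics <- list(starts = sol$starts, channel_weights = channel_weights)
  if ("emergency_boost" %in% names(bounds) &&
      !any(as.logical(waves$emergency_declared))) {
    diagnostics$unidentifiable <- "emergency_boost"
    warning("no emergency weeks in wave series: emergency_boost is ",
            "unidentifiable", call. = FALSE)
  }
  calibration_result(sol$par, sol$value, sol$n_evaluations, replicates,
                     "covid", diagnostics)
}
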