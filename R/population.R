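#' Marginal targets for a regional synthetic population
#'
#' Bundles the printed marginal statistics a regional synthetic IBD
#' population must reproduce: the total patient count, sex and condition
#' (ulcerative colitis vs Crohn's disease) proportions, and per
#' (condition x sex) cell the target mean and SD of age on a bounded age
#' window.
#'
#' @param region region label, e.g. `"tokyo"`.
#' @param total_patients positive total number of represented patients.
#' @param sex_proportions named numeric `c(male = , female = )`, summing to 1.
#' @param condition_proportions named numeric `c(UC = , CD = )`, summing to 1.
#' @param age_targets data.frame with columns `condition`, `sex`, `mean`,
#'   `sd`: one row per (condition x sex) cell.
#' @param age_bounds closed age interval in years (default `c(18, 74)`).
#' @return an object of class `marginal_target_set`.
#' @export
marginal_target_set <- function(region, total_patients, sex_proportions,
                                condition_proportions, age_targets,
                                age_bounds = c(18, 74)) {
  stopifnot(length(total_patients) == 1, total_patients > 0)
  check_props <- function(p, nms, what) {
    if (!all(nms %in% names(p))) {
      stop(sprintf("%s must be named %s", what, paste(nms, collapse = ", ")),
           call. = FALSE)
    }
    p <- p[nms]
    if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("%s must lie in [0,1] and sum to 1", what), call. = FALSE)
    }
    p
  }
  sex_proportions <- check_props(sex_proportions, c("male", "female"),
                                 "sex_proportions")
  condition_proportions <- check_props(condition_proportions, c("UC", "CD"),
                                       "condition_proportions")
  stopifnot(length(age_bounds) == 2, age_bounds[1] < age_bounds[2])
  need <- c("condition", "sex", "mean", "sd")
  if (!all(need %in% names(age_targets))) {
    stop("age_targets needs columns condition, sex, mean, sd", call. = FALSE)
  }
  if (any(age_targets$mean <= age_bounds[1]) ||
      any(age_targets$mean >= age_bounds[2])) {
    stop("age target means must lie strictly inside age_bounds", call. = FALSE)
  }
  if (any(age_targets$sd <= 0)) {
    stop("age target SDs must be > 0", call. = FALSE)
  }
  structure(
    list(region = region, total_patients = as.numeric(total_patients),
         sex_proportions = sex_proportions,
         condition_proportions = condition_proportions,
         age_targets = age_targets, age_bounds = as.numeric(age_bounds)),
    class = "marginal_target_set"
  )
}

#' Read a population marginal configuration from JSON
#'
#' The package ships `tokyo.json` and `hokkaido.json` under
#' `inst/extdata/population/` with the published regional marginals.
#'
#' @param path path to a JSON file with keys `region`, `total_patients`,
#'   `sex_proportions`, `condition_proportions`, `age_targets`, `age_bounds`.
#' @return a [marginal_target_set()].
#' @export
read_population_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("population config not found: %s", path), call. = FALSE)
  }
  cfg <- jsonlite::fromJSON(path)
  marginal_target_set(
    region = cfg$region,
    total_patients = cfg$total_patients,
    sex_proportions = unlist(cfg$sex_proportions),
    condition_proportions = unlist(cfg$condition_proportions),
    age_targets = as.data.frame(cfg$age_targets),
    age_bounds = as.numeric(cfg$age_bounds)
  )
}

#' Packaged regional marginal configuration
#'
#' @param region `"tokyo"` or `"hokkaido"`.
#' @return a [marginal_target_set()] for the requested region.
#' @export
regional_targets <- function(region = c("tokyo", "hokkaido")) {
  region <- match.arg(region)
  read_population_config(system.file("extdata", "population",
                                     paste0(region, ".json"),
                                     package = "ibddemand", mustWork = TRUE))
}

# largest-remainder apportionment; ties broken by position (lexicographic
# cell order), which makes the allocation fully deterministic
largest_remainder <- function(proportions, total) {
  ideal <- proportions * total
  base <- floor(ideal)
  left <- round(total - sum(base))
  if (left > 0) {
    rem <- ideal - base
    take <- order(-rem, seq_along(rem))[seq_len(left)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

#' Deterministic integer allocation of a total across (sex x condition) cells
#'
#' Allocation is hierarchical: the sex marginal is apportioned first, then the
#' condition split within each sex, each stage by largest remainder with
#' lexicographic tie-break (male before female, UC before CD). The hierarchy
#' guarantees that the printed sex marginal is reproduced exactly at every
#' total, which a flat allocation of product-form joint proportions does not.
#'
#' @param targets a [marginal_target_set()].
#' @param total nonnegative integer total to allocate.
#' @return data.frame with columns `sex`, `condition`, `count`; counts are
#'   nonnegative integers summing exactly to `total`.
#' @export
allocate_cell_counts <- function(targets, total) {
  stopifnot(inherits(targets, "marginal_target_set"))
  if (length(total) != 1 || is.na(total) || total < 0) {
    stop("total must be a single nonnegative count", call. = FALSE)
  }
  total <- as.numeric(total)
  by_sex <- largest_remainder(targets$sex_proportions, total)
  cells <- expand.grid(condition = c("UC", "CD"), sex = c("male", "female"),
                       stringsAsFactors = FALSE)[, c("sex", "condition")]
  cells <- cells[order(match(cells$sex, c("male", "female")),
                       match(cells$condition, c("UC", "CD"))), ]
  counts <- integer(4)
  for (s in 1:2) {
    within <- largest_remainder(targets$condition_proportions, by_sex[s])
    counts[(s - 1) * 2 + 1:2] <- within
  }
  cells$count <- counts
  rownames(cells) <- NULL
  cells
}

# per-cell truncated-normal fits, mean matched exactly, SD clamped to the
# attainable boundary when the printed pair is infeasible
cell_age_fits <- function(targets) {
  at <- targets$age_targets
  lo <- targets$age_bounds[1]
  hi <- targets$age_bounds[2]
  fits <- vector("list", nrow(at))
  for (i in seq_len(nrow(at))) {
    fits[[i]] <- withCallingHandlers(
      fit_truncnorm_moments(at$mean[i], at$sd[i], lo, hi,
                            on_infeasible = "nearest"),
      warning = function(w) {
        warning(sprintf("age cell %s/%s: %s", at$condition[i], at$sex[i],
                        conditionMessage(w)), call. = FALSE)
        invokeRestart("muffleWarning")
      }
    )
  }
  names(fits) <- paste(at$sex, at$condition, sep = ".")
  fits
}

#' Generate a weighted synthetic agent population from marginal targets
#'
#' Allocates `n_agents` across (sex x condition) cells deterministically
#' (see [allocate_cell_counts()]); each agent carries a weight equal to its
#' cell's full-scale target count divided by the number of agents in the
#' cell, so weighted totals and marginal shares reproduce the configuration
#' exactly. Ages are drawn from the cell's moment-matched truncated normal.
#' Severity, initial pathway stage, and treatment are assigned from the
#' stated initial-state fractions, and schedule timers are randomly phased to
#' avoid artificial synchronization of visits.
#'
#' @param targets a [marginal_target_set()].
#' @param n_agents number of agents (weighted representatives), default 1e5.
#' @param seed integer seed; identical seeds give identical populations.
#' @param initial_states list with elements `undiagnosed` and `symptomatic`
#'   (fractions of agents not yet diagnosed / currently seeking care; the
#'   rest are in continuous care), `severe` (fraction moderate-to-severe),
#'   and `biologic` (fraction of diagnosed agents on biologic maintenance).
#' @param params pathway parameters used only to phase initial timers
#'   (default [default_pathway_parameters()]).
#' @return data.frame of class `agent_population` with columns `agent_id`,
#'   `region`, `sex`, `age`, `condition`, `severity`, `state`, `treatment`,
#'   `weight`, `propensity` plus scheduling columns used by the simulator.
#' @export
generate_population <- function(targets, n_agents = 100000L, seed,
                                initial_states = list(undiagnosed = 0.30,
                                                      symptomatic = 0.02,
                                                      severe = 0.30,
                                                      biologic = 0.25),
                                params = default_pathway_parameters()) {
  stopifnot(inherits(targets, "marginal_target_set"), n_agents >= 1)
  if (n_agents > targets$total_patients) {
    stop("n_agents exceeds total_patients: weights would fall below 1",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  cells <- allocate_cell_counts(targets, n_agents)
  full <- allocate_cell_counts(targets, targets$total_patients)
  fits <- cell_age_fits(targets)
  lo <- targets$age_bounds[1]
  hi <- targets$age_bounds[2]

  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    k <- cells$count[i]
    if (k == 0) next
    key <- paste(cells$sex[i], cells$condition[i], sep = ".")
    at <- targets$age_targets
    j <- which(at$sex == cells$sex[i] & at$condition == cells$condition[i])
    if (length(j) != 1) {
      stop(sprintf("age_targets must contain exactly one row for %s", key),
           call. = FALSE)
    }
    fit <- fits[[paste(at$sex[j], at$condition[j], sep = ".")]]
    rows[[i]] <- data.frame(
      region = targets$region,
      sex = cells$sex[i],
      condition = cells$condition[i],
      age = rtruncnorm(k, fit$mu, fit$sigma, lo, hi),
      weight = full$count[i] / k,
      stringsAsFactors = FALSE
    )
  }
  agents <- do.call(rbind, rows)
  n <- nrow(agents)
  agents$agent_id <- seq_len(n)

  st <- initial_states
  u <- stats::runif(n)
  agents$state <- ifelse(u < st$undiagnosed, "undiagnosed_asymptomatic",
                  ifelse(u < st$undiagnosed + st$symptomatic,
                         "symptomatic_seeking_care", "diagnosed_continuous_care"))
  agents$severity <- ifelse(stats::runif(n) < st$severe,
                            "moderate_severe", "mild_moderate")
  diagnosed <- agents$state == "diagnosed_continuous_care"
  agents$treatment <- ifelse(!diagnosed, "none",
                             ifelse(stats::runif(n) < st$biologic,
                                    "biologic", "conventional"))
  agents$propensity <- 1

  # random phases so scheduled events are spread over their intervals
  vis_int <- ifelse(agents$severity == "moderate_severe",
                    params$visit_interval[["moderate_severe"]],
                    params$visit_interval[["mild_moderate"]])
  proc_int <- ifelse(agents$severity == "moderate_severe",
                     params$procedure_interval[["moderate_severe"]],
                     params$procedure_interval[["mild_moderate"]])
  agents$next_visit_due <- ifelse(diagnosed,
                                  floor(stats::runif(n) * vis_int), NA_real_)
  # timer phases span 1..interval so each cycle fires from week 0 onward
  agents$weeks_since_procedure <- ifelse(diagnosed,
                                         floor(stats::runif(n) * proc_int) + 1,
                                         NA_real_)
  agents$procedure_threshold <- ifelse(diagnosed, proc_int, NA_real_)
  onbio <- agents$treatment == "biologic"
  agents$weeks_since_biologic <- ifelse(onbio,
                                        floor(stats::runif(n) *
                                              params$biologic_interval) + 1,
                                        NA_real_)
  agents$biologic_threshold <- ifelse(onbio, params$biologic_interval,
                                      NA_real_)
  agents$ever_biologic <- onbio
  agents$weeks_since_onset <- ifelse(agents$state == "symptomatic_seeking_care",
                                     0, NA_real_)

  agents <- agents[, c("agent_id", "region", "sex", "age", "condition",
                       "severity", "state", "treatment", "weight",
                       "propensity", "next_visit_due",
                       "weeks_since_procedure", "procedure_threshold",
                       "weeks_since_biologic", "biologic_threshold",
                       "ever_biologic", "weeks_since_onset")]
  attr(agents, "targets") <- targets
  attr(agents, "seed") <- as.integer(seed)
  class(agents) <- c("agent_population", "data.frame")
  agents
}

#' Weighted marginal summary of an agent population
#'
#' Reports the weighted total, sex and condition shares, and per
#' (condition x sex) cell the weighted mean and SD of age. Shares sum to 1
#' within 1e-9. Cells with a single agent report an absent (NA) SD.
#'
#' @param agents an `agent_population` (or any data.frame with `sex`,
#'   `condition`, `age`, `weight`).
#' @return list with `total_weight`, `sex_shares`, `condition_shares`, and
#'   `age_by_cell` (data.frame with weighted `mean` and `sd`).
#' @export
population_summary <- function(agents) {
  if (is.null(agents) || nrow(agents) == 0) {
    stop("population_summary: empty agent collection", call. = FALSE)
  }
  w <- agents$weight
  tot <- sum(w)
  sex_shares <- vapply(c("male", "female"),
                       function(s) sum(w[agents$sex == s]) / tot, numeric(1))
  cond_shares <- vapply(c("UC", "CD"),
                        function(cc) sum(w[agents$condition == cc]) / tot,
                        numeric(1))
  cells <- expand.grid(condition = c("UC", "CD"), sex = c("male", "female"),
                       stringsAsFactors = FALSE)
  cells$mean <- NA_real_
  cells$sd <- NA_real_
  cells$weight <- NA_real_
  for (i in seq_len(nrow(cells))) {
    sel <- agents$condition == cells$condition[i] & agents$sex == cells$sex[i]
    if (!any(sel)) next
    wi <- w[sel]
    xi <- agents$age[sel]
    m <- sum(wi * xi) / sum(wi)
    cells$mean[i] <- m
    cells$weight[i] <- sum(wi)
    if (sum(sel) > 1) {
      cells$sd[i] <- sqrt(sum(wi * (xi - m)^2) / sum(wi))
    }
  }
  list(total_weight = tot, sex_shares = sex_shares,
       condition_shares = cond_shares, age_by_cell = cells)
}

#' Write / read an agent table as CSV
#'
#' The on-disk format keeps the identifying and demographic columns of the
#' agent record contract.
#'
#' @param agents an `agent_population`.
#' @param path output CSV path.
#' @return `write_agents` returns `path` invisibly; `read_agents` returns a
#'   data.frame.
#' @export
write_agents <- function(agents, path) {
  keep <- c("agent_id", "region", "sex", "age", "condition", "severity",
            "state", "weight")
  utils::write.csv(as.data.frame(agents)[, keep], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_agents
#' @param path input CSV path.
#' @export
read_agents <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
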