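#' Write / read a demand series as CSV
#'
#' The canonical on-disk contract is a CSV with header
#' `week_start,new_patients,total_patients,outpatient_visits,procedures,`
#' `biologics,vedolizumab_infusions,new_vedolizumab_starts`. Reading
#' accepts the columns in any order and reorders them canonically; a
#' missing column is a format error naming the expected header, and a gap
#' in the weekly dates is an error reporting the missing week.
#'
#' @param series a [demand_series()].
#' @param path CSV path.
#' @return `write_series` returns `path` invisibly; `read_series` returns a
#'   [demand_series()].
#' @export
write_series <- function(series, path) {
  df <- as.data.frame(series)[, c("week_start", series_channels())]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("series file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("week_start", series_channels())
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop(sprintf("series CSV format error: expected header %s (missing: %s)",
                 paste(need, collapse = ","),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df <- df[, need]
  df$week_start <- as.Date(df$week_start)
  df <- df[order(df$week_start), ]
  if (nrow(df) > 1) {
    gaps <- which(diff(df$week_start) != 7)
    if (length(gaps) > 0) {
      stop(sprintf("series has a gap: missing week starting %s",
                   format(df$week_start[gaps[1]] + 7)), call. = FALSE)
    }
  }
  do.call(demand_series, c(list(week_start = df$week_start),
                           as.list(df[series_channels()])))
}

#' Write an ensemble summary as CSV
#'
#' Header: `channel,week_start,min,q1,median,q3,max`.
#'
#' @param summary an `ensemble_summary` from [run_ensemble()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

validation_error <- function(msgs) {
  stop(structure(class = c("ibd_validation_error", "error", "condition"),
                 list(message = paste(msgs, collapse = "; "),
                      call = NULL)))
}

# schema-style validation: collect every violation, then fail once listing
# all offending keys
validate_config <- function(cfg, path) {
  msgs <- character()
  req <- function(key, ok, why) {
    if (!ok) msgs <<- c(msgs, sprintf("key '%s': %s", key, why))
  }
  req("command", !is.null(cfg$command) &&
        cfg$command %in% c("generate-population", "simulate", "calibrate",
                           "suite", "synthclaims"),
      "must be one of generate-population, simulate, calibrate, suite, synthclaims")
  if (!is.null(cfg$total_patients)) {
    req("total_patients", is.numeric(cfg$total_patients) &&
          cfg$total_patients > 0, "must be a positive count")
  }
  if (!is.null(cfg$n_agents)) {
    req("n_agents", is.numeric(cfg$n_agents) && cfg$n_agents >= 1,
        "must be >= 1")
  }
  if (!is.null(cfg$horizon)) {
    req("horizon", is.numeric(cfg$horizon) && cfg$horizon >= 1,
        "must be >= 1 week")
  }
  if (!is.null(cfg$n_weeks)) {
    req("n_weeks", is.numeric(cfg$n_weeks) && cfg$n_weeks >= 1,
        "must be >= 1 week")
  }
  if (identical(cfg$command, "generate-population") ||
      identical(cfg$command, "simulate")) {
    req("population", !is.null(cfg$population),
        "population config path is required")
    if (!is.null(cfg$population)) {
      pth <- resolve_path(cfg$population, path)
      req("population", file.exists(pth),
          sprintf("file not found: %s", pth))
    }
  }
  if (identical(cfg$command, "suite")) {
    req("suite", !is.null(cfg$suite), "suite config path is required")
  }
  if (length(msgs) > 0) validation_error(msgs)
  invisible(TRUE)
}

resolve_path <- function(p, config_path) {
  if (grepl("^(/|[A-Za-z]:)", p)) return(p)
  file.path(dirname(config_path), p)
}

#' Run a packaged workflow from a configuration file
#'
#' Dispatches on the config's `command` key (`generate-population`,
#' `simulate`, `calibrate`, `suite`, `synthclaims`), writes all outputs
#' into `out_dir`, and writes a run manifest (`manifest.json`) recording
#' config digests, seeds, package version, timestamps, the output file
#' listing, and the total number of simulation runs executed. Relative
#' paths inside the config resolve against the config file's directory.
#'
#' @param config_path path to a JSON configuration.
#' @param out_dir output directory (created if absent).
#' @param seed integer seed overriding the config's `seed` (optional).
#' @return the manifest, invisibly.
#' @export
run_from_config <- function(config_path, out_dir, seed = NULL) {
  if (!file.exists(config_path)) {
    stop(sprintf("config file not found: %s", config_path), call. = FALSE)
  }
  cfg <- jsonlite::fromJSON(config_path, simplifyDataFrame = FALSE)
  validate_config(cfg, config_path)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  t0 <- Sys.time()
  outputs <- character()
  total_runs <- 0L

  emit <- function(fname, writer) {
    p <- file.path(out_dir, fname)
    writer(p)
    outputs <<- c(outputs, p)
    p
  }

  if (cfg$command == "generate-population") {
    targets <- read_population_config(resolve_path(cfg$population,
                                                   config_path))
    agents <- generate_population(targets,
                                  n_agents = cfg$n_agents %||% 100000L,
                                  seed = seed)
    emit(sprintf("agents_%s.csv", targets$region),
         function(p) write_agents(agents, p))
  } else if (cfg$command == "simulate") {
    targets <- read_population_config(resolve_path(cfg$population,
                                                   config_path))
    agents <- generate_population(targets,
                                  n_agents = cfg$n_agents %||% 100000L,
                                  seed = seed)
    params <- if (is.null(cfg$pathway)) default_pathway_parameters()
              else read_pathway_config(resolve_path(cfg$pathway, config_path))
    horizon <- as.integer(cfg$horizon %||% 156L)
    mod <- if (is.null(cfg$scenario)) NULL
           else build_scenario_from_def(cfg$scenario, horizon)
    series <- run_simulation(agents, params, modifiers = mod,
                             horizon = horizon, seed = seed,
                             start_date = as.Date(cfg$start_date %||%
                                                  "2020-01-06"))
    total_runs <- 1L
    emit(sprintf("series_%s.csv", targets$region),
         function(p) write_series(series, p))
  } else if (cfg$command == "synthclaims") {
    truth <- claims_fixture(cfg$fixture %||% "tokyo")
    series <- generate_claims_series(truth, n_weeks = cfg$n_weeks %||% 304L,
                                     seed = seed)
    emit(sprintf("synthclaims_%s.csv", cfg$fixture %||% "tokyo"),
         function(p) write_series(series, p))
  } else if (cfg$command == "suite") {
    sc <- read_suite_config(resolve_path(cfg$suite, config_path))
    res <- run_crisis_suite(sc)
    total_runs <- res$manifest$total_runs
    for (nm in names(res$summaries)) {
      emit(sprintf("ensemble_%s.csv", nm),
           function(p) write_ensemble(res$summaries[[nm]], p))
    }
  } else if (cfg$command == "calibrate") {
    obs <- read_series(resolve_path(cfg$observed, config_path))
    targets <- read_population_config(resolve_path(cfg$population %||%
      system.file("extdata", "population", "tokyo.json",
                  package = "ibddemand"), config_path))
    agents <- generate_population(targets,
                                  n_agents = cfg$n_agents %||% 20000L,
                                  seed = seed)
    params <- if (is.null(cfg$pathway)) default_pathway_parameters()
              else read_pathway_config(resolve_path(cfg$pathway, config_path))
    bounds <- lapply(cfg$bounds, as.numeric)
    tgt <- calibration_target(targets$region, "pre_covid", obs,
                              range = range(obs$week_start))
    fit <- fit_baseline_growth(tgt, agents, params, bounds, seed,
                               n_starts = cfg$n_starts %||% 5L,
                               replicates = cfg$replicates %||% 3L)
    total_runs <- fit$n_evaluations * fit$replicates_per_evaluation
    emit("calibration.json", function(p) {
      jsonlite::write_json(list(par = as.list(fit$par),
                                objective_value = fit$objective_value,
                                n_evaluations = fit$n_evaluations,
                                replicates = fit$replicates_per_evaluation,
                                bounds = cfg$bounds),
                           p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
  }

  manifest <- list(
    command = cfg$command,
    config = list(path = config_path,
                  md5 = unname(tools::md5sum(config_path))),
    seed = seed,
    package_version = as.character(utils::packageVersion("ibddemand")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs,
    total_runs = total_runs
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
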