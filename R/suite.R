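#' Crisis-suite configuration
#'
#' A suite is a grid of scenario x region x replicate simulation runs. The
#' packaged full-scale configuration enumerates the published design — 3
#' crisis scenarios x 2 regions x 300 replicates = 1800 runs — and the
#' desk-scale configuration (3 x 2 x 5 = 30 runs) exercises the identical
#' code path at continuous-integration size.
#'
#' @param scenarios named list of scenario definitions; each is a list with
#'   `type` (`"pandemic"`, `"earthquake"` or `"financial_crisis"`) and the
#'   builder's parameters.
#' @param regions named list of region definitions; each is a list with
#'   `config` (population config path or a `marginal_target_set`) and
#'   optionally `n_agents`.
#' @param n_replicates replicate runs per scenario x region.
#' @param horizon weeks per run.
#' @param n_agents default agents per region.
#' @param params a [pathway_parameters()] (default packaged defaults).
#' @param base_seed integer seed for the whole suite.
#' @return object of class `suite_config`.
#' @export
suite_config <- function(scenarios, regions, n_replicates, horizon = 156L,
                         n_agents = 100000L,
                         params = default_pathway_parameters(),
                         base_seed = 1L) {
  stopifnot(length(scenarios) >= 1, length(regions) >= 1, n_replicates >= 1)
  structure(list(scenarios = scenarios, regions = regions,
                 n_replicates = as.integer(n_replicates),
                 horizon = as.integer(horizon),
                 n_agents = as.integer(n_agents), params = params,
                 base_seed = as.integer(base_seed)),
            class = "suite_config")
}

#' Read a suite configuration from JSON
#' @param path JSON file with keys `scenarios`, `regions`, `n_replicates`,
#'   and optionally `horizon`, `n_agents`, `base_seed`.
#' @return a [suite_config()].
#' @export
read_suite_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  # resolve relative file references against the config's own directory
  cfg$scenarios <- lapply(cfg$scenarios, function(def) {
    if (!is.null(def$waves) && is.character(def$waves)) {
      def$waves <- resolve_path(def$waves, path)
    }
    def
  })
  cfg$regions <- lapply(cfg$regions, function(rdef) {
    if (!is.null(rdef$config) && is.character(rdef$config)) {
      rdef$config <- resolve_path(rdef$config, path)
    }
    rdef
  })
  suite_config(
    scenarios = cfg$scenarios,
    regions = cfg$regions,
    n_replicates = cfg$n_replicates,
    horizon = cfg$horizon %||% 156L,
    n_agents = cfg$n_agents %||% 100000L,
    base_seed = cfg$base_seed %||% 1L
  )
}

#' Enumerate the runs of a suite without executing them
#'
#' @param config a [suite_config()].
#' @return list with `grid` (data.frame of scenario, region, replicate) and
#'   `total_runs`.
#' @export
enumerate_suite <- function(config) {
  stopifnot(inherits(config, "suite_config"))
  grid <- expand.grid(scenario = names(config$scenarios),
                      region = names(config$regions),
                      replicate = seq_len(config$n_replicates),
                      stringsAsFactors = FALSE)
  list(grid = grid, total_runs = nrow(grid))
}

build_scenario_from_def <- function(def, horizon) {
  switch(def$type,
    pandemic = {
      waves <- if (is.character(def$waves)) read_covid_waves(def$waves)
               else as.data.frame(def$waves)
      pr <- do.call(pandemic_response_params, def$response %||% list())
      mod <- build_pandemic_scenario(waves, pr)
      if (nrow(mod) < horizon) {
        pad <- identity_scenario(horizon)
        pad[seq_len(nrow(mod)), -1] <- mod[, -1]
        pad
      } else {
        mod
      }
    },
    earthquake = build_earthquake_scenario(horizon, def$start_week,
                                           def$severity, def$recovery_weeks),
    financial_crisis = build_financial_crisis_scenario(
      horizon, def$start_week, def$depth, def$duration_weeks,
      def$recovery_weeks),
    identity = identity_scenario(horizon),
    stop(sprintf("unknown scenario type: %s", def$type), call. = FALSE)
  )
}

#' Execute a crisis suite
#'
#' Runs every scenario x region combination as a seeded ensemble of
#' `n_replicates` runs and returns the per-combination ensemble summaries
#' together with a manifest recording the complete run count. Any failing
#' run aborts the suite with the failing combination named.
#'
#' @param config a [suite_config()].
#' @param capacity optional [capacity_model()] shared by all runs.
#' @return list with `summaries` (named list of `ensemble_summary`) and
#'   `manifest` (run grid, total run count, seeds).
#' @export
run_crisis_suite <- function(config, capacity = NULL) {
  stopifnot(inherits(config, "suite_config"))
  enum <- enumerate_suite(config)
  summaries <- list()
  combo_idx <- 0L
  for (rg in names(config$regions)) {
    rdef <- config$regions[[rg]]
    targets <- if (inherits(rdef$config, "marginal_target_set")) rdef$config
               else read_population_config(rdef$config)
    n_agents <- rdef$n_agents %||% config$n_agents
    agents <- generate_population(targets, n_agents = n_agents,
                                  seed = config$base_seed)
    for (sc in names(config$scenarios)) {
      combo_idx <- combo_idx + 1L
      mod <- tryCatch(
        build_scenario_from_def(config$scenarios[[sc]], config$horizon),
        error = function(e) {
          stop(sprintf("suite run failed for scenario=%s region=%s: %s",
                       sc, rg, conditionMessage(e)), call. = FALSE)
        })
      summ <- tryCatch(
        run_ensemble(list(agents = agents, params = config$params,
                          modifiers = mod, capacity = capacity,
                          horizon = config$horizon),
                     n_runs = config$n_replicates,
                     base_seed = config$base_seed + 100L * combo_idx),
        error = function(e) {
          stop(sprintf("suite run failed for scenario=%s region=%s: %s",
                       sc, rg, conditionMessage(e)), call. = FALSE)
        })
      summaries[[paste(sc, rg, sep = ".")]] <- summ
    }
  }
  manifest <- list(grid = enum$grid, total_runs = enum$total_runs,
                   n_replicates = config$n_replicates,
                   base_seed = config$base_seed,
                   horizon = config$horizon)
  list(summaries = summaries, manifest = manifest)
}
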