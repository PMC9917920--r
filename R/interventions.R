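#' Recovery-intervention specification
#'
#' An intervention restores a stated fraction of the disruption gap on its
#' target channels during its active window. Impacts are fractions of the
#' remaining gap to baseline: applying impact `a` to a multiplier `m` gives
#' `m + a * (1 - m)`. Messaging-type interventions act on demand only
#' (supply impact not applicable).
#'
#' @param name intervention label.
#' @param supply_impact fraction in `[0, 1]`, or `NA` when not applicable.
#' @param demand_impact fraction in `[0, 1]`.
#' @param supply_targets character subset of
#'   `c("s_outpatient", "s_procedures", "s_biologic")`.
#' @param demand_targets character subset of
#'   `c("d_care_seeking", "d_continuous", "d_biologic")`.
#' @param active_window length-2 integer week interval (0-based, inclusive),
#'   or `NULL` for always active.
#' @param description free-text description.
#' @return object of class `intervention_spec`.
#' @export
intervention_spec <- function(name, supply_impact = NA_real_, demand_impact,
                              supply_targets = character(),
                              demand_targets = c("d_care_seeking",
                                                 "d_continuous",
                                                 "d_biologic"),
                              active_window = NULL, description = "") {
  if (!is.na(supply_impact) &&
      (supply_impact < 0 || supply_impact > 1)) {
    stop("supply_impact must be in [0,1] or NA", call. = FALSE)
  }
  stopifnot(demand_impact >= 0, demand_impact <= 1)
  if (!is.na(supply_impact) && supply_impact > 0 &&
      length(supply_targets) == 0) {
    stop("supply_impact given but no supply_targets", call. = FALSE)
  }
  if (demand_impact > 0 && length(demand_targets) == 0) {
    stop("demand_impact given but no demand_targets", call. = FALSE)
  }
  bad_s <- setdiff(supply_targets,
                   c("s_outpatient", "s_procedures", "s_biologic"))
  bad_d <- setdiff(demand_targets,
                   c("d_care_seeking", "d_continuous", "d_biologic"))
  if (length(bad_s) || length(bad_d)) {
    stop("unknown intervention targets: ",
         paste(c(bad_s, bad_d), collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, supply_impact = supply_impact,
                 demand_impact = demand_impact,
                 supply_targets = supply_targets,
                 demand_targets = demand_targets,
                 active_window = active_window,
                 description = description),
            class = "intervention_spec")
}

#' Load the packaged catalogue of six recovery interventions
#'
#' Three messaging interventions (physician outreach 15%, system social
#' signaling 40%, national confidence building 60%) act on demand only;
#' three logistics interventions carry both impacts (simple navigation
#' assistance 5%/15%, barrier elimination 40%/40%, emergency response
#' infrastructure 60%/55% supply/demand). Custom catalogues may override
#' windows and targets; overriding the packaged impact values emits a
#' warning.
#'
#' @param path optional CSV path; defaults to the packaged catalogue.
#' @return named list of six [intervention_spec()] objects.
#' @export
load_intervention_catalog <- function(path = NULL) {
  packaged <- system.file("extdata", "interventions.csv",
                          package = "ibddemand", mustWork = TRUE)
  if (is.null(path)) path <- packaged
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(normalizePath(path), normalizePath(packaged))) {
    ref <- utils::read.csv(packaged, stringsAsFactors = FALSE)
    common <- intersect(df$name, ref$name)
    for (nm in common) {
      a <- df[df$name == nm, c("supply_impact", "demand_impact")]
      b <- ref[ref$name == nm, c("supply_impact", "demand_impact")]
      if (!isTRUE(all.equal(a, b, check.attributes = FALSE))) {
        warning(sprintf("impact values for '%s' differ from the packaged %s",
                        nm, "catalogue"), call. = FALSE)
      }
    }
  }
  split_targets <- function(x) {
    if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";")[[1]]
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    intervention_spec(
      name = df$name[i],
      supply_impact = df$supply_impact[i],
      demand_impact = df$demand_impact[i],
      supply_targets = split_targets(df$supply_targets[i]),
      demand_targets = split_targets(df$demand_targets[i]),
      description = df$description[i]
    )
  })
  stats::setNames(out, df$name)
}

#' Apply interventions to disrupted scenario modifiers
#'
#' Each intervention closes its impact fraction of the remaining gap to
#' baseline on its target channels, within its active window:
#' `m' = m + impact * (1 - m)`. Sequential application over the residual
#' gap is commutative — the combined restored fraction over several
#' interventions is `1 - prod(1 - impact_i)` — so the order of the list
#' does not matter. Multipliers already at or above 1 are unchanged.
#'
#' @param modifiers a [scenario_modifiers()].
#' @param interventions list of [intervention_spec()] (or a single one).
#' @return the modified [scenario_modifiers()].
#' @export
apply_interventions <- function(modifiers, interventions) {
  stopifnot(inherits(modifiers, "scenario_modifiers"))
  if (inherits(interventions, "intervention_spec")) {
    interventions <- list(interventions)
  }
  mod <- modifiers
  for (iv in interventions) {
    stopifnot(inherits(iv, "intervention_spec"))
    weeks <- mod$week
    if (!is.null(iv$active_window)) {
      active <- weeks >= iv$active_window[1] & weeks <= iv$active_window[2]
    } else {
      active <- rep(TRUE, length(weeks))
    }
    restore <- function(col, impact) {
      m <- mod[[col]]
      gap <- pmax(1 - m, 0)
      m[active] <- m[active] + impact * gap[active]
      mod[[col]] <<- pmin(m, pmax(mod[[col]], 1))
    }
    for (col in iv$demand_targets) restore(col, iv$demand_impact)
    if (!is.na(iv$supply_impact)) {
      for (col in iv$supply_targets) restore(col, iv$supply_impact)
    }
  }
  mod
}
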