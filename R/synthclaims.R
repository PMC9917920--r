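#' Ground truth for a synthetic weekly claims-aggregate series
#'
#' Defines the deterministic mean structure of an emulated claims series:
#' exponential growth of new diagnoses, prevalence as the accumulation of
#' new diagnoses, periodic utilization of visits/procedures/biologics tied
#' to prevalence, and an optional disruption with wave-shaped dips, partial
#' catch-up of deferred volume during recovery, and a damped second wave.
#' Observation noise is negative binomial (claims aggregates are
#' overdispersed counts).
#'
#' @param base_weekly_new_patients mean new diagnoses per week at week 0.
#' @param growth yearly growth factor g of new diagnoses (mean at week w is
#'   `base * g^(w/52)`).
#' @param base_total_patients prevalent (diagnosed) patients at week 0.
#' @param visit_interval,procedure_interval,biologic_interval weeks between
#'   events per prevalent patient (utilization rate = prevalence/interval).
#' @param biologic_share fraction of prevalent patients on biologic
#'   maintenance.
#' @param disruption `NULL`, or a list describing the dip: either
#'   `list(modifiers = <scenario_modifiers>)` giving explicit per-week
#'   multipliers (demand columns are mapped onto channels), or
#'   `list(onset_week =, depth =, recovery_weeks =, second_onset_week =,
#'   second_ratio =, biologic_bump =)` where `depth` is a scalar or named
#'   per-channel fraction in `[0, 1]`, the optional second wave repeats the
#'   profile scaled by `second_ratio`, and the optional `biologic_bump =
#'   c(height, weeks)` raises the biologic channel transiently above 1 at
#'   onset (stock-piling) before its dip.
#' @param catchup_rate fraction of the deferred-volume pool delivered per
#'   week, scaled by the current multiplier (recovery releases the backlog
#'   gradually). Scalar or named per channel: deferred scheduled events
#'   (visits, procedures, dispensings) are re-attempted weekly (rate near
#'   1), while deferred care seeking is re-attempted at the care-seeking
#'   hazard (rate well below 1).
#' @param dispersion overdispersion factor phi of the count noise: weekly
#'   observations are negative binomial with variance `phi * mean`
#'   (quasi-Poisson-style NB1 parameterization, the usual model for claims
#'   aggregates; `phi <= 1` degrades to Poisson). Scalar or named per
#'   channel.
#' @return object of class `claims_ground_truth`.
#' @export
claims_ground_truth <- function(base_weekly_new_patients,
                                growth = 1.08,
                                base_total_patients,
                                visit_interval = 8,
                                procedure_interval = 26,
                                biologic_interval = 8,
                                biologic_share = 0.25,
                                disruption = NULL,
                                catchup_rate = 0.5,
                                dispersion = 10) {
  stopifnot(base_weekly_new_patients >= 0, growth > 0,
            base_total_patients >= 0,
            visit_interval >= 1, procedure_interval >= 1,
            biologic_interval >= 1,
            biologic_share >= 0, biologic_share <= 1,
            all(catchup_rate >= 0), all(catchup_rate <= 1),
            all(dispersion > 0))
  if (!is.null(disruption) && is.null(disruption$modifiers)) {
    d <- disruption$depth
    if (any(d < 0) || any(d > 1)) {
      stop("disruption depths must be in [0,1]", call. = FALSE)
    }
    if (!is.null(disruption$second_ratio)) {
      stopifnot(disruption$second_ratio >= 0, disruption$second_ratio <= 1)
    }
  }
  structure(list(base_weekly_new_patients = base_weekly_new_patients,
                 growth = growth,
                 base_total_patients = base_total_patients,
                 visit_interval = visit_interval,
                 procedure_interval = procedure_interval,
                 biologic_interval = biologic_interval,
                 biologic_share = biologic_share,
                 disruption = disruption,
                 catchup_rate = catchup_rate,
                 dispersion = dispersion),
            class = "claims_ground_truth")
}

# per-channel multiplier matrix (n_weeks x 4: new, visits, procedures, bio)
claims_multipliers <- function(truth, n_weeks) {
  chans <- c("new_patients", "outpatient_visits", "procedures", "biologics")
  m <- matrix(1, n_weeks, 4, dimnames = list(NULL, chans))
  dis <- truth$disruption
  if (is.null(dis)) return(m)
  if (!is.null(dis$modifiers)) {
    mod <- as.data.frame(dis$modifiers)
    k <- min(nrow(mod), n_weeks)
    m[seq_len(k), "new_patients"] <- mod$d_care_seeking[seq_len(k)]
    m[seq_len(k), "outpatient_visits"] <- mod$d_continuous[seq_len(k)]
    m[seq_len(k), "procedures"] <- mod$d_continuous[seq_len(k)]
    m[seq_len(k), "biologics"] <- mod$d_biologic[seq_len(k)]
    return(m)
  }
  depth <- dis$depth
  if (is.null(names(depth))) {
    depth <- stats::setNames(rep(depth[1], 4), chans)
  } else {
    full <- stats::setNames(rep(0, 4), chans)
    full[names(depth)] <- depth
    depth <- full
  }
  dip <- function(m, onset, scale) {
    for (ch in chans) {
      d0 <- depth[[ch]] * scale
      for (k in 0:dis$recovery_weeks) {
        w <- onset + k
        if (w >= 0 && w < n_weeks) {
          m[w + 1, ch] <- min(m[w + 1, ch],
                              1 - d0 * (1 - k / dis$recovery_weeks))
        }
      }
    }
    m
  }
  m <- dip(m, dis$onset_week, 1)
  if (!is.null(dis$second_onset_week)) {
    m <- dip(m, dis$second_onset_week,
             if (is.null(dis$second_ratio)) 1 else dis$second_ratio)
  }
  if (!is.null(dis$biologic_bump)) {
    h <- dis$biologic_bump[1]
    wk <- dis$biologic_bump[2]
    idx <- dis$onset_week + seq_len(wk) - 1
    idx <- idx[idx >= 0 & idx < n_weeks]
    m[idx + 1, "biologics"] <- 1 + h
  }
  m
}

#' Deterministic mean curves of a synthetic claims series
#'
#' The noise-free weekly means implied by a [claims_ground_truth()]:
#' undisrupted new diagnoses grow exponentially; each flow channel is
#' multiplied by its disruption profile and augmented by catch-up delivery
#' from a deferred pool (inflow `mean * (1 - m)`, outflow
#' `pool * catchup_rate * m`); prevalence accumulates realized diagnoses.
#'
#' @param truth a [claims_ground_truth()].
#' @param n_weeks series length.
#' @return data.frame of weekly mean values per channel.
#' @export
claims_mean_curve <- function(truth, n_weeks) {
  stopifnot(n_weeks >= 1)
  w <- seq_len(n_weeks) - 1
  m <- claims_multipliers(truth, n_weeks)
  new_base <- truth$base_weekly_new_patients * truth$growth^(w / 52)

  cr <- truth$catchup_rate
  rate_for <- function(ch) {
    if (!is.null(names(cr)) && ch %in% names(cr)) return(cr[[ch]])
    if (is.null(names(cr))) cr[1] else max(cr)
  }
  catchup <- function(base, mult, rate) {
    out <- numeric(n_weeks)
    pool <- 0
    for (t in seq_len(n_weeks)) {
      deferred <- base[t] * (1 - min(mult[t], 1))
      released <- pool * rate * min(mult[t], 1)
      out[t] <- base[t] * mult[t] + released
      pool <- pool + deferred - released
    }
    out
  }

  new_mean <- catchup(new_base, m[, "new_patients"], rate_for("new_patients"))
  total_mean <- truth$base_total_patients + cumsum(new_mean)
  # each new diagnosis also generates a new-patient visit and a diagnostic
  # workup procedure on top of the continuous-care utilization
  visits_base <- total_mean / truth$visit_interval + new_mean
  proc_base <- total_mean / truth$procedure_interval + new_mean
  bio_base <- total_mean * truth$biologic_share / truth$biologic_interval
  visits_mean <- catchup(visits_base, m[, "outpatient_visits"],
                         rate_for("outpatient_visits"))
  proc_mean <- catchup(proc_base, m[, "procedures"], rate_for("procedures"))
  bio_mean <- catchup(bio_base, m[, "biologics"], rate_for("biologics"))
  new_starts_mean <- new_mean * truth$biologic_share

  data.frame(week = w,
             new_patients = new_mean,
             total_patients = total_mean,
             outpatient_visits = visits_mean,
             procedures = proc_mean,
             biologics = bio_mean,
             vedolizumab_infusions = bio_mean,
             new_vedolizumab_starts = new_starts_mean)
}

#' Generate a synthetic weekly claims series
#'
#' Draws negative-binomial observations around [claims_mean_curve()]. The
#' same truth and seed give an identical series; the Monte-Carlo mean over
#' replicates converges to the mean curve.
#'
#' @param truth a [claims_ground_truth()].
#' @param n_weeks series length (>= 1).
#' @param seed integer seed.
#' @param start_date date of week 0 (default 2015-01-05).
#' @param region optional region label.
#' @return a [demand_series()].
#' @export
generate_claims_series <- function(truth, n_weeks, seed,
                                   start_date = as.Date("2015-01-05"),
                                   region = NULL) {
  mc <- claims_mean_curve(truth, n_weeks)
  set.seed(as.integer(seed))
  disp <- truth$dispersion
  phi_for <- function(ch) {
    if (!is.null(names(disp)) && ch %in% names(disp)) return(disp[[ch]])
    if (is.null(names(disp))) disp[1] else max(disp)
  }
  noisy <- function(ch) {
    mu <- mc[[ch]]
    phi <- phi_for(ch)
    out <- numeric(length(mu))
    pos <- mu > 0
    if (phi <= 1) {
      out[pos] <- stats::rpois(sum(pos), mu[pos])
    } else {
      # NB1: var = phi * mu  =>  size = mu / (phi - 1)
      out[pos] <- stats::rnbinom(sum(pos), size = mu[pos] / (phi - 1),
                                 mu = mu[pos])
    }
    out
  }
  ws <- start_date + 7 * (seq_len(n_weeks) - 1)
  demand_series(ws,
                new_patients = noisy("new_patients"),
                total_patients = noisy("total_patients"),
                outpatient_visits = noisy("outpatient_visits"),
                procedures = noisy("procedures"),
                biologics = noisy("biologics"),
                vedolizumab_infusions = noisy("vedolizumab_infusions"),
                new_vedolizumab_starts = noisy("new_vedolizumab_starts"),
                region = region)
}

#' Packaged synthetic claims fixture presets
#'
#' Two region-flavoured presets: the larger, faster-recovering preset and a
#' smaller preset with a later, slower recovery and a transient increase in
#' biologic dispensing at disruption onset before its dip (stock-piling
#' followed by a supply drop). Both are synthetic stand-ins with known
#' ground truth; no claims data are shipped.
#'
#' @param region `"tokyo"` or `"hokkaido"` flavour.
#' @return a [claims_ground_truth()].
#' @export
claims_fixture <- function(region = c("tokyo", "hokkaido")) {
  region <- match.arg(region)
  path <- system.file("extdata", "synthclaims",
                      paste0(region, "_fixture.json"),
                      package = "ibddemand", mustWork = TRUE)
  cfg <- jsonlite::fromJSON(path)
  dis <- cfg$disruption
  if (!is.null(dis)) {
    dis <- list(onset_week = dis$onset_week,
                depth = unlist(dis$depth),
                recovery_weeks = dis$recovery_weeks,
                second_onset_week = dis$second_onset_week,
                second_ratio = dis$second_ratio,
                biologic_bump = if (is.null(dis$biologic_bump)) NULL else
                  unlist(dis$biologic_bump))
  }
  claims_ground_truth(
    base_weekly_new_patients = cfg$base_weekly_new_patients,
    growth = cfg$growth,
    base_total_patients = cfg$base_total_patients,
    visit_interval = cfg$visit_interval,
    procedure_interval = cfg$procedure_interval,
    biologic_interval = cfg$biologic_interval,
    biologic_share = cfg$biologic_share,
    disruption = dis,
    catchup_rate = unlist(cfg$catchup_rate),
    dispersion = unlist(cfg$dispersion)
  )
}
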