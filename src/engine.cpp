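// Weekly agent-based simulation core for the IBD clinical pathway.
//
// One call advances every agent through `horizon` weeks under per-week
// demand multipliers (attendance scaling) and supply multipliers (capacity
// scaling), with an aggregate backlog queue per service. Uses R's RNG so a
// set.seed() before the call makes runs bitwise reproducible.
//
// Weekly update order (fixed, documented in the package vignette):
//   1. symptom onset (non-depleting arrival process, hazard * g^(t/52))
//   2. outpatient demand collection: new-patient care seeking (attendance
//      scaled by d_care_seeking) and due continuous-care visits (scaled by
//      d_visits); pending diagnosed-queue clearance
//   3. outpatient service (capacity, backlog admission, rationing)
//   4. procedure demand (diagnostic workups of served new visits + due
//      monitoring procedures) and procedure service; diagnosis draws
//   5. biologic demand (due maintenance dispensings) and service
//   6. timers advance
//
// Capacity-unserved scheduled events enter the backlog and the agent
// reschedules on its normal cycle (the event is delivered late from the
// backlog and counted on delivery). Unserved new-patient visits leave the
// agent waiting in the queue (pending flag, no fresh care-seeking draws);
// pending agents are cleared in proportion to backlog service. The weekly
// conservation identity demanded = served + backlog + abandoned holds
// exactly per service.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct ServiceAccount {
  double backlog = 0.0;
  double cum_demanded = 0.0;
  double cum_served = 0.0;
  double cum_abandoned = 0.0;
};

// Admission/rationing arithmetic for one service-week. Returns the serve
// fraction applied to this week's demanders; `admitted` is backlog mass
// admitted this week (served at the same fraction).
struct ServiceWeek {
  double fraction;
  double admitted;
  double served_backlog;
};

ServiceWeek open_service(ServiceAccount& acc, double demanded, double capacity,
                         double supply_mult, double backlog_rate) {
  ServiceWeek sw;
  sw.admitted = acc.backlog * backlog_rate;
  double cap = capacity * supply_mult;  // Inf * 1 stays Inf; Inf * 0 = NaN
  if (capacity == R_PosInf && supply_mult == 0.0) cap = 0.0;
  double pool = demanded + sw.admitted;
  if (!R_finite(cap) || pool <= cap) {
    sw.fraction = 1.0;
  } else if (pool <= 0.0) {
    sw.fraction = 1.0;
  } else {
    sw.fraction = cap / pool;
  }
  sw.served_backlog = sw.admitted * sw.fraction;
  return sw;
}

void close_service(ServiceAccount& acc, const ServiceWeek& sw, double demanded,
                   double served_new, double abandonment_rate,
                   double& abandoned_out) {
  acc.cum_demanded += demanded;
  acc.cum_served += served_new + sw.served_backlog;
  acc.backlog = acc.backlog - sw.served_backlog + (demanded - served_new);
  if (acc.backlog < 0) acc.backlog = 0;  // guard fp dust
  double abandoned = acc.backlog * abandonment_rate;
  acc.backlog -= abandoned;
  acc.cum_abandoned += abandoned;
  abandoned_out = abandoned;
}

inline int jitter_interval(double base, double sd) {
  double v = base;
  if (sd > 0) v += R::rnorm(0.0, sd);
  int iv = (int)std::lround(v);
  return iv < 1 ? 1 : iv;
}

}  // namespace

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(IntegerVector stage,      // 0 undiag, 1 symptomatic, 2 diagnosed
              IntegerVector severity,   // 0 mild_moderate, 1 moderate_severe
              IntegerVector treatment,  // 0 none, 1 conventional, 2 biologic
              NumericVector weight, NumericVector propensity,
              IntegerVector ever_biologic, IntegerVector pending_diag,
              IntegerVector next_visit_due, IntegerVector weeks_since_proc,
              IntegerVector thr_proc, IntegerVector weeks_since_bio,
              IntegerVector thr_bio, List params, NumericMatrix demand_mult,
              NumericMatrix supply_mult, NumericVector capacity,
              double backlog_rate, double abandonment_rate, int horizon,
              int week_offset, double initial_undiag_weight,
              NumericVector initial_backlog) {
  const int n = stage.size();
  const double onset_hazard = as<double>(params["symptom_onset_hazard"]);
  const double growth = as<double>(params["growth"]);
  const double care_seek = as<double>(params["care_seeking_hazard"]);
  const double diag_prob = as<double>(params["diagnosis_probability"]);
  NumericVector visit_int = params["visit_interval"];       // mild, severe
  NumericVector proc_int = params["procedure_interval"];    // mild, severe
  const double bio_int = as<double>(params["biologic_interval"]);
  const double bio_init = as<double>(params["biologic_initiation_hazard"]);
  const double sev_prog = as<double>(params["severity_progression_hazard"]);
  const double jit_sd = as<double>(params["interval_jitter_sd"]);

  // working copies (inputs stay untouched so the wrapper can reuse them)
  IntegerVector st = clone(stage), sev = clone(severity), tr = clone(treatment);
  IntegerVector evb = clone(ever_biologic), pend = clone(pending_diag);
  IntegerVector nvd = clone(next_visit_due), wsp = clone(weeks_since_proc);
  IntegerVector tp = clone(thr_proc), wsb = clone(weeks_since_bio);
  IntegerVector tb = clone(thr_bio);

  ServiceAccount acc_out, acc_proc, acc_bio;
  acc_out.backlog = initial_backlog[0];
  acc_proc.backlog = initial_backlog[1];
  acc_bio.backlog = initial_backlog[2];

  const int n_cols = 23;
  NumericMatrix out(horizon, n_cols);

  double undiag_w = 0.0, total_diag_w = 0.0;
  for (int i = 0; i < n; ++i) {
    if (st[i] == 0) undiag_w += weight[i];
    if (st[i] == 2) total_diag_w += weight[i];
  }
  double undiag_w0 = initial_undiag_weight > 0 ? initial_undiag_weight
                                               : undiag_w;

  std::vector<int> want_newvisit, want_visit, want_proc_diag, want_proc_mon,
      want_bio;
  want_newvisit.reserve(n);
  want_visit.reserve(n);

  RNGScope rng;

  for (int t = 0; t < horizon; ++t) {
    const double week_abs = (double)(week_offset + t);
    const double hw = onset_hazard * std::pow(growth, week_abs / 52.0);
    const double d_cs = demand_mult(t, 0);
    const double d_vis = demand_mult(t, 1);
    const double d_bio = demand_mult(t, 2);

    double new_pat = 0, visits = 0, procedures = 0, biologics = 0,
           new_starts = 0;
    double def_cs = 0, def_vis = 0, def_proc = 0, def_bio = 0;
    want_newvisit.clear();
    want_visit.clear();
    want_proc_diag.clear();
    want_proc_mon.clear();
    want_bio.clear();

    // 1. symptom onset: expected weekly onsets = hw * initial undiagnosed
    //    weight, regardless of how far the synthetic reservoir has drained
    double p_onset = 0.0;
    if (undiag_w > 0) {
      p_onset = hw * undiag_w0 / undiag_w;
      if (p_onset > 1) p_onset = 1;
    }
    // clearance fraction for pending new-patient agents, from last week's
    // outpatient backlog service (computed inside service block below);
    // initialized per week before use
    // 2. collect outpatient demand
    double dem_out = 0.0;
    for (int i = 0; i < n; ++i) {
      if (st[i] == 0) {
        if (p_onset > 0 && R::unif_rand() < p_onset) {
          st[i] = 1;
          undiag_w -= weight[i];
        }
      }
      if (st[i] == 1 && !pend[i]) {
        if (R::unif_rand() < care_seek * propensity[i]) {
          if (R::unif_rand() < d_cs) {
            want_newvisit.push_back(i);
            dem_out += weight[i];
          } else {
            def_cs += weight[i];
          }
        }
      } else if (st[i] == 2) {
        if (sev[i] == 0 && sev_prog > 0 && R::unif_rand() < sev_prog) {
          sev[i] = 1;
        }
        if (sev[i] == 1 && tr[i] == 1 && bio_init > 0 &&
            R::unif_rand() < bio_init) {
          tr[i] = 2;
          wsb[i] = (int)bio_int;  // first dispensing due immediately
          tb[i] = (int)bio_int;
        }
        if (t + week_offset >= nvd[i]) {
          if (R::unif_rand() < d_vis) {
            want_visit.push_back(i);
            dem_out += weight[i];
          } else {
            // skipped, not retried: the patient waits for the next
            // regular visit, so sustained demand suppression produces a
            // sustained reduction in served visits
            def_vis += weight[i];
            nvd[i] = week_offset + t + jitter_interval(visit_int[sev[i]],
                                                       jit_sd);
          }
        }
      }
    }

    // 3. outpatient service
    ServiceWeek sw_out = open_service(acc_out, dem_out, capacity[0],
                                      supply_mult(t, 0), backlog_rate);
    // pending new-patient agents cleared in proportion to backlog service
    double p_clear = 0.0;
    if (acc_out.backlog > 0) p_clear = sw_out.served_backlog / acc_out.backlog;
    if (p_clear > 1) p_clear = 1;
    double served_out = 0.0;
    for (int idx : want_newvisit) {
      bool served = sw_out.fraction >= 1.0 || R::unif_rand() < sw_out.fraction;
      if (served) {
        visits += weight[idx];
        served_out += weight[idx];
        want_proc_diag.push_back(idx);
      } else {
        pend[idx] = 1;  // waits in the queue; demand carried by backlog
      }
    }
    for (int idx : want_visit) {
      bool served = sw_out.fraction >= 1.0 || R::unif_rand() < sw_out.fraction;
      if (served) {
        visits += weight[idx];
        served_out += weight[idx];
        int vi = jitter_interval(visit_int[sev[idx]], jit_sd);
        nvd[idx] = week_offset + t + vi;
      } else {
        // delivered later from the backlog; agent resumes its normal cycle
        int vi = jitter_interval(visit_int[sev[idx]], jit_sd);
        nvd[idx] = week_offset + t + vi;
      }
    }
    // pending agents cleared by backlog service proceed to diagnosis workup
    if (p_clear > 0) {
      for (int i = 0; i < n; ++i) {
        if (pend[i] && st[i] == 1 && R::unif_rand() < p_clear) {
          pend[i] = 0;
          want_proc_diag.push_back(i);
        }
      }
    }
    visits += sw_out.served_backlog;  // late-delivered visits count now
    double abn_out = 0.0;
    close_service(acc_out, sw_out, dem_out, served_out, abandonment_rate,
                  abn_out);
    // abandonment also releases a matching share of pending agents
    if (abandonment_rate > 0) {
      for (int i = 0; i < n; ++i) {
        if (pend[i] && R::unif_rand() < abandonment_rate) pend[i] = 0;
      }
    }

    // 4. procedures: diagnostic workups for served new visits + due
    //    monitoring procedures of diagnosed agents
    double dem_proc = 0.0;
    for (int idx : want_proc_diag) dem_proc += weight[idx];
    for (int i = 0; i < n; ++i) {
      if (st[i] == 2 && wsp[i] >= tp[i]) {
        if (R::unif_rand() < d_vis) {
          want_proc_mon.push_back(i);
          dem_proc += weight[i];
        } else {
          // skipped monitoring procedure: next one a full cycle later
          def_proc += weight[i];
          wsp[i] = 0;
          tp[i] = jitter_interval(proc_int[sev[i]], jit_sd);
        }
      }
    }
    ServiceWeek sw_proc = open_service(acc_proc, dem_proc, capacity[1],
                                       supply_mult(t, 1), backlog_rate);
    double served_proc = 0.0;
    for (int idx : want_proc_diag) {
      bool served =
          sw_proc.fraction >= 1.0 || R::unif_rand() < sw_proc.fraction;
      if (served) {
        procedures += weight[idx];
        served_proc += weight[idx];
        if (R::unif_rand() < diag_prob) {
          st[idx] = 2;
          tr[idx] = 1;
          new_pat += weight[idx];
          total_diag_w += weight[idx];
          nvd[idx] = week_offset + t + jitter_interval(visit_int[sev[idx]],
                                                       jit_sd);
          wsp[idx] = 0;
          tp[idx] = jitter_interval(proc_int[sev[idx]], jit_sd);
          wsb[idx] = 0;
          tb[idx] = (int)bio_int;
        }
      }
      // unserved diagnostic workup stays in the backlog; the agent remains
      // symptomatic and will express care seeking again
    }
    for (int idx : want_proc_mon) {
      bool served =
          sw_proc.fraction >= 1.0 || R::unif_rand() < sw_proc.fraction;
      if (served) {
        procedures += weight[idx];
        served_proc += weight[idx];
      }
      // served or backlogged, the agent resumes its normal monitoring cycle
      wsp[idx] = 0;
      tp[idx] = jitter_interval(proc_int[sev[idx]], jit_sd);
    }
    procedures += sw_proc.served_backlog;
    double abn_proc = 0.0;
    close_service(acc_proc, sw_proc, dem_proc, served_proc, abandonment_rate,
                  abn_proc);

    // 5. biologic dispensing
    double dem_bio = 0.0;
    for (int i = 0; i < n; ++i) {
      if (st[i] == 2 && tr[i] == 2 && wsb[i] >= tb[i]) {
        if (R::unif_rand() < d_bio) {
          want_bio.push_back(i);
          dem_bio += weight[i];
        } else {
          def_bio += weight[i];
        }
      }
    }
    ServiceWeek sw_bio = open_service(acc_bio, dem_bio, capacity[2],
                                      supply_mult(t, 2), backlog_rate);
    double served_bio = 0.0;
    for (int idx : want_bio) {
      bool served = sw_bio.fraction >= 1.0 || R::unif_rand() < sw_bio.fraction;
      if (served) {
        biologics += weight[idx];
        served_bio += weight[idx];
        if (!evb[idx]) {
          new_starts += weight[idx];
          evb[idx] = 1;
        }
      }
      wsb[idx] = 0;
      tb[idx] = jitter_interval(bio_int, jit_sd);
    }
    biologics += sw_bio.served_backlog;
    double abn_bio = 0.0;
    close_service(acc_bio, sw_bio, dem_bio, served_bio, abandonment_rate,
                  abn_bio);

    // 6. timers advance
    for (int i = 0; i < n; ++i) {
      if (st[i] == 2) {
        wsp[i] += 1;
        if (tr[i] == 2) wsb[i] += 1;
      }
    }

    out(t, 0) = new_pat;
    out(t, 1) = total_diag_w;
    out(t, 2) = visits;
    out(t, 3) = procedures;
    out(t, 4) = biologics;
    out(t, 5) = biologics;   // vedolizumab infusions == dispensings
    out(t, 6) = new_starts;  // new vedolizumab starts
    out(t, 7) = def_cs;
    out(t, 8) = def_vis;
    out(t, 9) = def_proc;
    out(t, 10) = def_bio;
    out(t, 11) = acc_out.backlog;
    out(t, 12) = acc_proc.backlog;
    out(t, 13) = acc_bio.backlog;
    out(t, 14) = acc_out.cum_demanded;
    out(t, 15) = acc_proc.cum_demanded;
    out(t, 16) = acc_bio.cum_demanded;
    out(t, 17) = acc_out.cum_served;
    out(t, 18) = acc_proc.cum_served;
    out(t, 19) = acc_bio.cum_served;
    out(t, 20) = acc_out.cum_abandoned;
    out(t, 21) = acc_proc.cum_abandoned;
    out(t, 22) = acc_bio.cum_abandoned;
  }

  return List::create(
      _["tally"] = out,
      _["state"] = List::create(
          _["stage"] = st, _["severity"] = sev, _["treatment"] = tr,
          _["ever_biologic"] = evb, _["pending_diag"] = pend,
          _["next_visit_due"] = nvd, _["weeks_since_proc"] = wsp,
          _["thr_proc"] = tp, _["weeks_since_bio"] = wsb, _["thr_bio"] = tb),
      _["backlog"] = NumericVector::create(acc_out.backlog, acc_proc.backlog,
                                           acc_bio.backlog),
      _["undiagnosed_weight0"] = undiag_w0);
}
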