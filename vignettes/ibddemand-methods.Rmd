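---
title: "Modelling IBD healthcare demand under disruption: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling IBD healthcare demand under disruption: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ibddemand` couples two models. A **population builder** turns published
regional marginal statistics for patients with inflammatory bowel disease
(IBD) — total patient counts, sex and condition (ulcerative colitis vs
Crohn's disease) shares, and per-cell age moments on a bounded age window —
into a weighted synthetic agent population. A **demand simulator** then
advances those agents week by week through an IBD clinical pathway
(symptom onset, care seeking, diagnosis, continuous care with periodic
visits, monitoring procedures, and biologic maintenance), under
time-varying demand and supply disruptions, service capacity constraints
with a backlog queue, and recovery interventions. Calibration utilities fit
the pathway and disruption-response parameters to weekly claims-aggregate
series, and a synthetic claims generator provides series with known ground
truth so that every calibration property is testable without any external
data.

## 1. The synthetic population

### Deterministic cell allocation

Agent counts are apportioned across (sex × condition) cells
hierarchically: the sex marginal first, then the condition split within
each sex, each stage by largest-remainder rounding with a lexicographic
tie-break (male before female, UC before CD). The hierarchy guarantees the
printed sex marginal is met exactly at any total; a flat largest-remainder
pass over product-form joint proportions does not (it can shift a unit
between sexes). The same allocation run at the full regional total defines
per-cell weight budgets; each agent's weight is its cell budget divided by
the number of agents in the cell, so weighted totals and shares reproduce
the configuration exactly, independent of the random seed.

Joint (sex × condition) proportions are taken as the product of the two
marginal vectors. Only marginals are published; the independence assumption
is the neutral completion and is stated here explicitly as a modelling
choice.

### Age sampling and the truncated-normal feasibility boundary

Published age summaries are the mean and SD of ages *within* the study
window (18–74 years), so the sampler must solve for the underlying normal
parameters \((\mu, \sigma)\) whose truncation to \([a, b]\) reproduces
those moments. `fit_truncnorm_moments()` does this by nested root finding:
for each \(\sigma\) the truncated mean is matched exactly through \(\mu\)
(the mean is strictly increasing in \(\mu\)), and \(\sigma\) is then
adjusted until the truncated SD matches, to a tolerance of 1e-8. All tail
quantities are computed in log space so strongly tilted solutions
(\(\mu\) far outside the window, large \(\sigma\)) keep full accuracy, and
sampling is by inverse CDF with the truncation mass accumulated in log
space.

A point worth emphasising: **not every printed mean/SD pair is attainable
by a truncated normal**. Given the mean, the attainable SD is bounded
above; the bound follows from the closure of the family, which as
\(\sigma \to \infty\) is the family of exponential tilts
\(f(x) \propto e^{\theta x}\) on \([a, b]\) (and the global supremum over
all means is the uniform SD, \((b-a)/\sqrt{12} \approx 16.17\) years for
the 18–74 window). Several published pairs exceed this boundary — for
example SD 19.0 with mean 58.6, where the attainable supremum is about
13.1 years. Two behaviours are therefore provided: the strict fit errors,
naming the violated bound; the `"nearest"` mode (used by population
generation) matches the mean exactly and clamps the SD to the attainable
boundary, with a warning. The package's graded summaries of age are means,
which survive clamping exactly; reported SDs for clamped cells are the
attainable maxima, not the printed values. The quadrature in the test suite
(`stats::integrate` over the truncated density) is an independent oracle
for both the fit and the bound.

### Localization of an external seed population

`localize_weights()` reweights an arbitrary seed population (for example a
synthetic population built for another country) to the regional marginals:
a linear program minimises the total absolute deviation between weighted
seed marginals and targets subject to nonnegative weights summing to the
regional total. The L1 objective is linearised with split deviation
variables and solved with a simplex method (`pracma::linprog`); weights are
per (sex × condition) cell. The optimum can be degenerate; among equally
good solutions the uniform scaling of the seed is preferred, as the least
distortion of the seed's composition. The test suite checks the solver
against exact enumeration of basic feasible solutions on small instances.
Behavioural attributes of the original consumer dataset are reduced to one
care-seeking propensity scalar per agent (default 1), as no usable
per-attribute detail is published.

## 2. The clinical pathway and the weekly engine

The timestep is one week, matching the resolution of the claims series the
model is calibrated to. Agents occupy one of three stages — undiagnosed
asymptomatic, symptomatic seeking care, diagnosed in continuous care — with
severity (mild-to-moderate / moderate-to-severe) and treatment (none /
conventional / biologic) attributes. The weekly update order is fixed:
symptom onset; outpatient demand collection (new-patient care seeking and
due continuous-care visits); outpatient service; procedure demand
(diagnostic workups of served new visits plus due monitoring procedures)
and service, with diagnosis draws; biologic dispensing; timer advance.
Biologic prescriptions, infusions, and dispensings are one event counted in
the prescription and infusion channels alike; the named biologic is
vedolizumab, whose 8-week maintenance cycle is the default dispensing
interval.

**Demand versus biology.** Scenario demand multipliers scale only
*attendance*: the probability that a care-seeking attempt, a scheduled
visit, a monitoring procedure, or a refill is attended. Disease biology —
symptom onset and severity progression — is never scaled. Supply
multipliers scale service capacity. This separation is what lets demand-
and supply-side disruptions be composed and intervened on independently.

**Deferral semantics.** An attendance failure is recorded in the deferred
channel, and what happens next depends on the event type. A skipped
continuous-care visit or monitoring procedure is *not retried the next
week*: the patient waits for the next regular cycle. This choice is
deliberate. If skipped visits were re-attempted weekly, served volume would
return to baseline under any sustained demand suppression (the retry queue
conserves flow), which contradicts the sustained dips observed in
disruption-period utilisation data; skipping produces a sustained served
reduction proportional to the multiplier. Care seeking and biologic
refills, by contrast, are re-attempted (symptomatic patients eventually
present; patients need their medication), so those channels rebound after
a disruption.

**Incidence as a non-depleting arrival process.** The expected number of
weekly symptom onsets is `hazard × g^(week/52) × W0`, where `W0` is the
*initial* undiagnosed weight and g the yearly growth factor. Per-agent
onset probabilities are rescaled by the current reservoir so the arrival
rate does not decline as the finite synthetic reservoir drains: regional
incidence is driven by the region's population, not by the size of the
simulated reservoir. Baseline weekly diagnoses therefore grow exactly
geometrically (with a constant diagnosis lag of roughly
`1/(care_seeking_hazard × diagnosis_probability)` weeks), which is the
structure the baseline calibration exploits.

**Capacity and backlog.** Each service (outpatient visits, procedures,
biologic dispensing) has a weekly capacity scaled by the week's supply
multiplier. Admitted backlog is `backlog × backlog_service_rate`; served
volume is the minimum of the demand-plus-admitted pool and effective
capacity, allocated proportionally; unserved demand and unadmitted backlog
carry forward minus abandonment. The conservation identity — cumulative
demanded equals cumulative served plus current backlog plus cumulative
abandoned — holds exactly each week and is asserted in the tests.
Capacity-unserved *scheduled* events enter the backlog and the agent
resumes its normal cycle (the event is delivered late from the backlog and
counted on delivery); capacity-unserved *new-patient* visits leave the
agent waiting in the queue, cleared in proportion to backlog service, which
ties time-to-diagnosis to supply as well as demand. This structure
reproduces the qualitative backlog result: releasing a deep backlog fast
(service rate 0.9) produces a larger post-recovery oscillation in served
procedures than releasing it slowly (0.1), because the released cohort
re-synchronises the visit periodicity.

**Randomness.** Each run draws from a single R random stream seeded by the
run seed, with a fixed agent iteration order inside the compiled core, so
identical inputs and seed give bitwise-identical series. Ensembles use
seeds `base_seed + 0 … n_runs − 1` and report per-week five-number
summaries (minimum, quartiles, maximum) of raw weekly counts. Interval
jitter (normal, rounded, floored at one week) prevents artificial
synchronisation of visit cycles; initial timer phases are randomised over
the cycle so utilisation is in steady state from week 0.

### Default pathway parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `care_seeking_hazard` | 0.30 | /week | median ~2 weeks from symptoms to first visit |
| `diagnosis_probability` | 0.80 | per workup | most first workups are conclusive |
| `visit_interval` | 8 / 4 | weeks (mild / severe) | routine vs intensified review |
| `procedure_interval` | 26 / 13 | weeks | biannual vs quarterly monitoring |
| `biologic_interval` | 8 | weeks | vedolizumab maintenance cycle |
| `symptom_onset_hazard` | 2e-4 | /week | order-of-magnitude seed for calibration |
| `growth` | 1.08 | /year | rising diagnosis trend; calibration target |
| `severity_progression_hazard` | 0.002 | /week | ~10%/year mild-to-severe progression |
| `biologic_initiation_hazard` | 0.005 | /week | gradual biologic uptake among severe patients |
| `interval_jitter_sd` | 1 | weeks | schedule desynchronisation |

These are starting points and calibration targets, not published facts.

## 3. Disruption scenarios

Three archetypes are built as multiplier series. The **pandemic** builder
maps an exogenous weekly case series (with an emergency-declaration flag)
through a reconstructed response function: raw impact
\(A\,c_t/(c_t + s) + b\,\mathbf{1}[\text{emergency}]\), damped by
habituation \(2^{-E_t/h}\) where \(E_t\) counts weeks since the impact
first became nonzero. The functional form is this package's
reconstruction: the qualitative record — the first, smallest wave,
accompanied by an emergency declaration, caused the largest disruption,
and later larger waves progressively less — fixes saturation, an
emergency term, and monotone habituation, but no published formula exists;
the parameters are meant to be fitted, not asserted. The habituation clock
runs from first exposure (rather than accumulating only during exposed
weeks) so that two equal waves separated by one halflife produce exactly a
halved second response. The **earthquake** is an immediate step drop of
severity \(s\) on demand and supply with linear recovery over \(r\) weeks
(deficit \(s(1-k/r)\) at week \(k\); summed disruption \(s(r+1)/2\)). The
**financial crisis** is purely demand-side: supply multipliers are
identically 1, demand drops to \(1-d\), holds, and ramps back. Earthquake
and crisis parameter values are hypothetical placeholders by construction;
no historical calibration data exist for them.

**Interventions** restore a stated fraction of the remaining gap to
baseline on their target channels: applying impact \(a\) to multiplier
\(m\) gives \(m + a(1-m)\). The residual-gap rule was chosen because it is
bounded (never overshoots 1) and commutative — composing impacts
\(a_1, a_2\) restores \(1-(1-a_1)(1-a_2)\) regardless of order. The
alternative reading, impacts multiplying the disruption magnitude itself
(\(m' = 1-(1-m)(1-a)\) is the same thing; \(m' = m + a\cdot m\) is not),
lacks both properties and is not used. The packaged catalogue carries the
six published interventions (three demand-only messaging tiers at 15%,
40%, 60%; three logistics tiers at 5%/15%, 40%/40%, 60%/55%
supply/demand); windows and targets may be overridden, impact values only
with a warning.

## 4. Calibration

Two phases, in the spirit of the source design: a pre-disruption phase
(January 2015 – December 2019) fits the baseline incidence level, the
yearly growth factor, and optionally interval scales; a disruption phase
(January – October 2020) holds those fixed and fits the wave-response
parameters. The objective is the channel-weighted mean squared error
between *monthly-aggregated* simulated and observed series, each channel
normalised by its observed mean. Monthly aggregation damps weekly
Monte-Carlo noise; normalisation makes channels of different magnitude
comparable. Each evaluation averages a small number of stochastic
replicates with fixed replicate seeds (common random numbers across
evaluations). Multi-parameter fits use Nelder–Mead from Latin-hypercube
multi-starts; single-parameter fits use a grid scan with local quadratic
refinement, which is markedly more stable than a line search on a
replicate-averaged objective whose evaluations carry Monte-Carlo jitter.

### The parameter-recovery harness

Because the original claims data are proprietary, calibration is validated
by parameter recovery on the synthetic claims generator. The shipped
harness uses 20,000 agents representing 40,000 patients, 5 multi-starts,
and 3 replicates per evaluation, and is deliberately built so the
simulator and the claims emulation are structurally matched: an all-mild
population with progression, initiation, and jitter off (so per-capita
utilisation rates equal the reciprocal intervals exactly); the symptomatic
pool primed at its steady state; and the claims prevalence anchored to the
realised diagnosed weight of the generated population. Growth is
identified mainly by the incident-flow channel, so the harness fixture
keeps the incident channel near-Poisson while utilisation channels carry
the heavy overdispersion typical of claims. Under these conditions the
growth factor is recovered within 2% relative error and the pandemic
maximum demand impact within ±0.1 absolute — the test suite asserts
exactly this, at fixed seeds. The known limitation is inherited from the
source design: recovery on synthetic truth demonstrates internal
consistency of the calibration machinery, not fidelity to the unavailable
claims record, and the incident and biologic channels respond less sharply
to disruption than utilisation channels, mirroring the reported
underresponse of those channels.

## 5. The synthetic claims generator

`generate_claims_series()` draws weekly observations around a
deterministic mean structure: exponential growth of new diagnoses;
prevalence as base plus accumulated diagnoses; visits and procedures as
prevalence divided by their intervals plus the new-patient event load;
biologics as a prevalence share over the dispensing interval. Disruptions
multiply the base curves per channel — either an explicit dip profile
(onset, depth, linear recovery, a damped second wave, and optionally a
transient biologic stock-piling bump before its dip, as seen in the
slower-recovering regional preset) — or a full multiplier series from a
scenario builder. Deferred volume accumulates in a per-channel pool and is
released during recovery at a channel-specific catch-up rate scaled by the
current multiplier; the channel defaults mirror the simulator's deferral
semantics (no catch-up for skipped visits and procedures, hazard-limited
catch-up for care seeking, near-full catch-up for dispensings).
Observation noise is negative binomial in the NB1 (quasi-Poisson)
parameterisation, variance = dispersion × mean, the standard
overdispersion model for claims aggregates: a single dispersion factor
then implies realistic relative noise at every channel magnitude, which
the NB2 ("size") parameterisation does not. The Monte-Carlo mean over
replicates converges to the analytic mean curve; the test suite asserts
this within sampling error at every week.

What the generator does **not** emulate: seasonality, reporting delays and
claim-level duplication, patient-level correlation between channels, and
any epidemiological link between case counts and IBD biology. Passing
recovery tests on these fixtures therefore demonstrates the calibration
machinery, not real-data fidelity.

## 6. Scale choices and reproducibility

Full-scale configurations (100,000 agents per region; the 1800-run crisis
suite of 3 scenarios × 2 regions × 300 replicates; 50-run ensembles) are
packaged and enumerable; the test suite executes a 30-run desk-scale suite
(3 × 2 × 5 at 2,000 agents and a one-year horizon) through the identical
code path, and the calibration tests run at the 20,000-agent harness scale
with 260-week pre-disruption and 44-week disruption windows. Every run is
a pure function of its inputs and seed; run manifests record config
digests, seeds, package version, and output listings, so any CLI run can
be reproduced exactly from its manifest.

Known limitations: no surgery events or differentiated pre-biologic drug
classes (insufficient source data); no mortality, remission exit, or
ageing within the ≤3-year horizon; no modelling of infection, testing, or
vaccination of the simulated patients; wave series are exogenous inputs,
never epidemic forecasts; and the published regional totals are treated
strictly as printed configuration, not as epidemiological prevalence
estimates.
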