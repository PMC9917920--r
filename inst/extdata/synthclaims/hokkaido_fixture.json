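{
  "region": "hokkaido",
  "base_weekly_new_patients": 6,
  "growth": 1.05,
  "base_total_patients": 4000,
  "visit_interval": 8,
  "procedure_interval": 26,
  "biologic_interval": 8,
  "biologic_share": 0.25,
  "catchup_rate": { "new_patients": 0.15, "outpatient_visits": 0.0, "procedures": 0.0, "biologics": 0.5 },
  "dispersion": { "new_patients": 2, "total_patients": 10, "outpatient_visits": 10, "procedures": 10, "biologics": 10 },
  "disruption": {
    "onset_week": 271,
    "depth": { "new_patients": 0.5, "outpatient_visits": 0.45, "procedures": 0.5, "biologics": 0.35 },
    "recovery_weeks": 24,
    "second_onset_week": 287,
    "second_ratio": 0.5,
    "biologic_bump": [0.15, 4]
  }
}
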