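{
  "region": "tokyo",
  "base_weekly_new_patients": 40,
  "growth": 1.08,
  "base_total_patients": 24000,
  "visit_interval": 8,
  "procedure_interval": 26,
  "biologic_interval": 8,
  "biologic_share": 0.25,
  "catchup_rate": { "new_patients": 0.3, "outpatient_visits": 0.0, "procedures": 0.0, "biologics": 1.0 },
  "dispersion": { "new_patients": 2, "total_patients": 10, "outpatient_visits": 10, "procedures": 10, "biologics": 10 },
  "disruption": {
    "onset_week": 268,
    "depth": { "new_patients": 0.5, "outpatient_visits": 0.4, "procedures": 0.45, "biologics": 0.2 },
    "recovery_weeks": 12,
    "second_onset_week": 284,
    "second_ratio": 0.4
  }
}
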