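{
  "region": "tokyo",
  "total_patients": 4873585,
  "sex_proportions": { "male": 0.561, "female": 0.439 },
  "condition_proportions": { "UC": 0.565, "CD": 0.435 },
  "age_targets": [
    { "condition": "UC", "sex": "male",   "mean": 52.7, "sd": 15.5 },
    { "condition": "UC", "sex": "female", "mean": 52.0, "sd": 15.6 },
    { "condition": "CD", "sex": "male",   "mean": 61.4, "sd": 8.3 },
    { "condition": "CD", "sex": "female", "mean": 52.2, "sd": 16.9 }
  ],
  "age_bounds": [18, 74]
}
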