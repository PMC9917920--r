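{
  "n_replicates": 5,
  "horizon": 52,
  "n_agents": 2000,
  "base_seed": 20201101,
  "scenarios": {
    "pandemic": {
      "type": "pandemic",
      "waves": "../waves/two_waves_2020.csv",
      "response": {
        "case_saturation": 2000,
        "max_demand_impact": 0.4,
        "max_supply_impact": 0.3,
        "emergency_boost": 0.2,
        "adaptation_halflife": 26
      }
    },
    "earthquake": {
      "type": "earthquake",
      "start_week": 8,
      "severity": 0.8,
      "recovery_weeks": 10
    },
    "financial_crisis": {
      "type": "financial_crisis",
      "start_week": 8,
      "depth": 0.3,
      "duration_weeks": 26,
      "recovery_weeks": 13
    }
  },
  "regions": {
    "tokyo": { "config": "../population/tokyo.json" },
    "hokkaido": { "config": "../population/hokkaido.json" }
  }
}
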