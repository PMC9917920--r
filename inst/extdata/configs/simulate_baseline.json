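{
  "command": "simulate",
  "population": "../population/tokyo.json",
  "n_agents": 5000,
  "horizon": 52,
  "seed": 1,
  "start_date": "2020-01-06"
}
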