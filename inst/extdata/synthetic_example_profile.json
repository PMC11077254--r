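{
  "laterality": "bilateral_or_head",
  "pitch_hz": 4000,
  "tll_db_hl": 60,
  "mml_db_hl": 50,
  "ri": "positive",
  "duration_months": 24,
  "tonal": true
}
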