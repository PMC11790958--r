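{
  "type": "csv",
  "required_columns": ["tether", "looped", "rate_kbp_s", "excluded"]
}
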