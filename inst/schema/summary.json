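{
  "type": "json",
  "required_fields": ["experiment_id", "n_tethers", "n_looped",
                      "fraction_looped", "acquisition_span"]
}
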