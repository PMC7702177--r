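{
  "$comment": "bcokit dialect schema: error bounds are free-form records per the standard.",
  "type": "object",
  "required": ["empirical_error", "algorithmic_error"],
  "properties": {
    "empirical_error": {"type": "object"},
    "algorithmic_error": {"type": "object"}
  }
}
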