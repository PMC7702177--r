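{
  "$comment": "bcokit dialect schema: parameter settings keyed to description-domain steps by step_number.",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["step_number", "param", "value"],
    "properties": {
      "step_number": {"type": "integer"},
      "param": {"type": "string"},
      "value": {"type": "string"}
    }
  }
}
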