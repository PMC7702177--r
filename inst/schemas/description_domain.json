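{
  "$comment": "bcokit dialect schema for the BCO description domain. pipeline step input_list/output_list entries are port identifier strings in this dialect.",
  "type": "object",
  "required": ["keywords", "pipeline_steps"],
  "properties": {
    "keywords": {"type": "array", "items": {"type": "string"}},
    "platform": {"type": "array", "items": {"type": "string"}},
    "xref": {"type": "array"},
    "pipeline_steps": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["step_number", "name", "description", "input_list", "output_list"],
        "properties": {
          "step_number": {"type": "integer"},
          "name": {"type": "string"},
          "description": {"type": "string"},
          "version": {"type": "string"},
          "input_list": {"type": "array", "items": {"type": "string"}},
          "output_list": {"type": "array", "items": {"type": "string"}}
        }
      }
    }
  }
}
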