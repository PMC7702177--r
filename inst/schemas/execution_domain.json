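{
  "$comment": "bcokit dialect schema for the BCO execution domain.",
  "type": "object",
  "required": ["script", "script_driver", "software_prerequisites", "external_data_endpoints", "environment_variables"],
  "properties": {
    "script": {"type": "array", "items": {"type": "string"}},
    "script_driver": {"type": "string"},
    "software_prerequisites": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "version"],
        "properties": {
          "name": {"type": "string"},
          "version": {"type": "string"},
          "uri": {"type": "string"}
        }
      }
    },
    "external_data_endpoints": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "url"],
        "properties": {
          "name": {"type": "string"},
          "url": {"type": "string"}
        }
      }
    },
    "environment_variables": {"type": "object"}
  }
}
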