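{
  "$comment": "bcokit dialect schema for the BCO input/output domain.",
  "type": "object",
  "required": ["input_subdomain", "output_subdomain"],
  "properties": {
    "input_subdomain": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["uri"],
        "properties": {
          "uri": {
            "type": "object",
            "required": ["uri"],
            "properties": {
              "uri": {"type": "string"},
              "filename": {"type": "string"},
              "access_time": {"type": "string"}
            }
          }
        }
      }
    },
    "output_subdomain": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["uri"],
        "properties": {
          "uri": {
            "type": "object",
            "required": ["uri"],
            "properties": {
              "uri": {"type": "string"},
              "filename": {"type": "string"},
              "access_time": {"type": "string"}
            }
          }
        }
      }
    }
  }
}
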