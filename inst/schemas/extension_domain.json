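{
  "$comment": "bcokit dialect schema: extension records are schema-tagged opaque trees.",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["extension_schema"],
    "properties": {
      "extension_schema": {"type": "string"}
    }
  }
}
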