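{
  "$comment": "bcokit dialect schema for BCO top-level fields (checked as 'structure' category).",
  "type": "object",
  "required": ["object_id", "spec_version", "etag"],
  "properties": {
    "object_id": {"type": "string"},
    "spec_version": {"type": "string"},
    "etag": {"type": "string", "pattern": "^[0-9a-f]{64}$"}
  }
}
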