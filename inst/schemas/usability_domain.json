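{
  "$comment": "bcokit dialect schema: usability domain is a list of free-text statements.",
  "type": "array",
  "items": {"type": "string"}
}
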