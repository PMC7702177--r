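{
  "$comment": "bcokit dialect schema for the BCO provenance domain, informed by IEEE 2791-2020; not the normative 2791 schema file.",
  "type": "object",
  "required": ["name", "version", "license", "created", "modified"],
  "properties": {
    "name": {"type": "string"},
    "version": {"type": "string"},
    "license": {"type": "string"},
    "created": {"type": "string"},
    "modified": {"type": "string"},
    "derived_from": {"type": "string"},
    "obsolete_after": {"type": "string"},
    "embargo": {"type": "object"},
    "contributors": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "contribution"],
        "properties": {
          "name": {"type": "string"},
          "affiliation": {"type": "string"},
          "email": {"type": "string"},
          "orcid": {"type": "string"},
          "contribution": {"type": "array", "items": {"type": "string"}}
        }
      }
    },
    "review": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["status"],
        "properties": {
          "status": {
            "type": "string",
            "enum": ["unreviewed", "in-review", "approved", "rejected", "suspended"]
          },
          "reviewer": {"type": "object"},
          "date": {"type": "string"},
          "reviewer_comment": {"type": "string"}
        }
      }
    }
  }
}
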