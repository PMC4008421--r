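{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "safetycode interpretation report",
  "type": "object",
  "required": ["kb_version", "profile_summary", "allele_calls", "rule_matches"],
  "properties": {
    "kb_version": { "type": "string" },
    "profile_summary": {
      "type": "object",
      "required": ["known", "unknown", "total"],
      "properties": {
        "known": { "type": "integer", "minimum": 0 },
        "unknown": { "type": "integer", "minimum": 0 },
        "total": { "type": "integer", "minimum": 0 }
      }
    },
    "allele_calls": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["gene", "label", "status", "conflict", "supporting_atoms"],
        "properties": {
          "gene": { "type": "string" },
          "label": { "type": "string" },
          "status": { "enum": ["TRUE", "FALSE", "UNKNOWN"] },
          "conflict": { "type": "boolean" },
          "supporting_atoms": { "type": "string",
            "description": "comma-joined tag atoms (rsNNN_X)" }
        }
      }
    },
    "rule_matches": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["rule_id", "status", "message", "source", "missing_markers"],
        "properties": {
          "rule_id": { "type": "string" },
          "status": { "enum": ["TRUE", "FALSE", "UNKNOWN"] },
          "message": { "type": "string" },
          "source": { "type": "string" },
          "missing_markers": { "type": "string",
            "description": "comma-joined rsids that left the condition UNKNOWN; empty otherwise" }
        }
      }
    }
  }
}
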