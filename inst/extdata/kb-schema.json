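{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "safetycode knowledge base",
  "description": "Pharmacogenomic knowledge base: marker panel, star-allele (tag-SNP) definitions, and clinical decision-support rules. Marker order defines the panel order and therefore the safety-code bit layout.",
  "type": "object",
  "required": ["version", "build", "markers", "haplotypes", "rules"],
  "properties": {
    "version": { "type": "string" },
    "build": { "type": "string", "description": "reference genome label, e.g. GRCh37" },
    "markers": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["rsid", "chromosome", "position", "reference", "allowed"],
        "properties": {
          "rsid": { "type": "string", "pattern": "^rs[0-9]+$" },
          "chromosome": { "type": "string", "pattern": "^([1-9]|1[0-9]|2[0-2]|X|Y|MT)$" },
          "position": { "type": "integer", "minimum": 1 },
          "reference": { "type": "string", "enum": ["A", "C", "G", "T"] },
          "allowed": {
            "type": "array", "minItems": 2, "maxItems": 4, "uniqueItems": true,
            "items": { "type": "string", "enum": ["A", "C", "G", "T"] },
            "description": "first element must equal reference"
          }
        }
      }
    },
    "haplotypes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["gene", "label", "sufficient", "necessary"],
        "properties": {
          "gene": { "type": "string" },
          "label": { "type": "string", "description": "allele name, e.g. *3" },
          "sufficient": { "$ref": "#/$defs/atomList", "minItems": 1 },
          "necessary": { "$ref": "#/$defs/atomList" },
          "meta": { "type": "object" }
        }
      }
    },
    "rules": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["rule_id", "condition", "message"],
        "properties": {
          "rule_id": { "type": "string" },
          "condition": { "$ref": "#/$defs/condition" },
          "message": { "type": "string", "minLength": 1 },
          "source": { "type": "string" }
        }
      }
    },
    "panel_genes": { "type": "array", "items": { "type": "string" } }
  },
  "$defs": {
    "atom": { "type": "string", "pattern": "^rs[0-9]+_[ACGT]$" },
    "atomList": { "type": "array", "items": { "$ref": "#/$defs/atom" } },
    "condition": {
      "oneOf": [
        { "type": "object", "required": ["and"],
          "properties": { "and": { "type": "array", "minItems": 1,
            "items": { "$ref": "#/$defs/condition" } } },
          "additionalProperties": false },
        { "type": "object", "required": ["has_some"],
          "properties": { "has_some": { "$ref": "#/$defs/atom" } },
          "additionalProperties": false },
        { "type": "object", "required": ["has_exactly"],
          "properties": { "has_exactly": { "type": "object",
            "required": ["n", "atom"],
            "properties": { "n": { "type": "integer", "minimum": 0, "maximum": 2 },
                            "atom": { "$ref": "#/$defs/atom" } } } },
          "additionalProperties": false },
        { "type": "object", "required": ["has_haplotype"],
          "properties": { "has_haplotype": { "type": "string",
            "pattern": "^[^*]+\\*.+$" } },
          "additionalProperties": false }
      ]
    }
  }
}
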