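{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "barcodeEval run summary",
  "type": "object",
  "required": ["tool", "seed", "model", "reps", "support_threshold", "loci"],
  "properties": {
    "tool": {"const": "barcodeEval"},
    "seed": {"type": "integer"},
    "model": {"enum": ["k2p", "p"]},
    "reps": {"type": "integer", "minimum": 0},
    "support_threshold": {"type": "number"},
    "loci": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["stats"],
        "properties": {
          "stats": {"type": "array"},
          "gap": {"type": "array"},
          "locus_gap": {"type": ["boolean", "null"]},
          "undefined_pairs": {"type": "integer"},
          "monophyly": {"type": "array"},
          "newick": {"type": "string"}
        }
      }
    },
    "combinations": {"type": "array"},
    "skipped": {"type": "array"}
  }
}
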