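{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "endotyper report",
  "description": "Night-level OSA endotype report produced by write_report()",
  "type": "object",
  "required": ["status", "code", "metadata"],
  "properties": {
    "status": { "enum": ["ok", "failed"] },
    "code": { "type": "string" },
    "message": { "type": "string" },
    "metadata": {
      "type": "object",
      "required": ["package", "version", "seed", "config"],
      "properties": {
        "package": { "const": "endotyper" },
        "version": { "type": "string" },
        "seed": { "type": "integer" },
        "cohort": { "type": ["string", "null"] },
        "config": { "type": "object" },
        "inputs": { "type": "object" }
      }
    },
    "night_traits": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["trait", "estimate", "n_windows", "flag"],
        "properties": {
          "trait": {
            "enum": ["vpassive", "vmin", "vactive", "compensation",
                     "arousal_threshold", "lg1", "lgn"]
          },
          "estimate": { "type": ["number", "null"] },
          "ci_lo": { "type": ["number", "null"] },
          "ci_hi": { "type": ["number", "null"] },
          "n_windows": { "type": "integer" },
          "flag": { "type": "string" },
          "label": { "type": ["string", "null"] }
        }
      }
    },
    "windows": { "type": "array" },
    "endogram": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["drive_median", "vent_median", "n_breaths"]
      }
    },
    "surrogate_indices": { "type": "object" },
    "fit": { "type": "object" },
    "warnings": { "type": "array" }
  }
}
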