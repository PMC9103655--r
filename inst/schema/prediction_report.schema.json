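{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "ligfish prediction report",
  "description": "Structured output of render_structured(): one document per prediction request, holding the query, the method, a provenance block, ordered summary rows and one similarity-analysis detail section per reported target.",
  "type": "object",
  "required": ["document", "layout_version", "query", "method", "provenance", "summary", "detail"],
  "properties": {
    "document": { "const": "prediction_report" },
    "layout_version": { "type": "string" },
    "query": {
      "type": "object",
      "required": ["canonical_smiles"],
      "properties": { "canonical_smiles": { "type": "string" } }
    },
    "method": { "enum": ["target_fishing", "bioactivity_profiling"] },
    "provenance": {
      "type": "object",
      "required": ["library", "params"],
      "properties": {
        "library": {
          "type": "object",
          "properties": {
            "source_name": { "type": "string" },
            "source_version": { "type": "string" },
            "built": { "type": "string" },
            "n_targets": { "type": "integer" },
            "n_ligands": { "type": "integer" },
            "n_activities": { "type": "integer" }
          }
        },
        "params": { "type": "object" },
        "fishing_params": { "type": "object" }
      }
    },
    "summary": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["rank", "target_id", "name"],
        "properties": {
          "rank": { "type": "integer" },
          "target_id": { "type": "string" },
          "name": { "type": "string" },
          "score": { "type": "integer", "minimum": 0, "maximum": 13 },
          "reliable": { "type": "boolean" },
          "IC50": { "type": ["number", "null"] },
          "EC50": { "type": ["number", "null"] },
          "Ki": { "type": ["number", "null"] },
          "Kd": { "type": ["number", "null"] },
          "sigma_p": { "type": "number", "minimum": 0 },
          "best_type": { "enum": ["IC50", "EC50", "Ki", "Kd"] }
        }
      }
    },
    "detail": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["target_id", "evidence"],
        "properties": {
          "target_id": { "type": "string" },
          "evidence": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["ligand_id", "canonical_smiles", "mean_similarity",
                           "similarities", "over_threshold"],
              "properties": {
                "ligand_id": { "type": "string" },
                "canonical_smiles": { "type": "string" },
                "mean_similarity": { "type": "number", "minimum": 0, "maximum": 1 },
                "similarities": {
                  "type": "object",
                  "description": "exactly the 13 fingerprint kinds, in panel order",
                  "additionalProperties": { "type": "number", "minimum": 0, "maximum": 1 },
                  "minProperties": 13,
                  "maxProperties": 13
                },
                "over_threshold": {
                  "type": "object",
                  "additionalProperties": { "type": "boolean" },
                  "minProperties": 13,
                  "maxProperties": 13
                },
                "best_type": { "enum": ["IC50", "EC50", "Ki", "Kd", null] },
                "best_value_nM": { "type": ["number", "null"] }
              }
            }
          }
        }
      }
    }
  }
}
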