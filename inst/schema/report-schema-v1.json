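{
  "version": 1,
  "description": "Structural schema for lousepop pipeline reports: required fields and their types. 'any' admits alternative shapes (e.g. a fit replaced by a diagnostic note).",
  "required": {
    "meta": {
      "type": "object",
      "required": {
        "tool": "string",
        "version": "string",
        "seed": "any",
        "timestamp": "string",
        "inputs": {
          "type": "object",
          "required": {
            "counts": {
              "type": "object",
              "required": { "path": "string", "md5": "string" }
            },
            "schedule": {
              "type": "object",
              "required": { "path": "string", "md5": "string" }
            }
          }
        },
        "config": {
          "type": "object",
          "required": { "min_expected": "number", "tol": "number", "max_age": "any" }
        }
      }
    },
    "aggregation": {
      "type": "object",
      "required": {
        "summary": {
          "type": "object",
          "required": {
            "n_hosts": "number",
            "n_infested": "number",
            "prevalence": "number",
            "total": "number",
            "mean_intensity": "number",
            "mean_abundance": "number",
            "count_range": "number",
            "variance": "number",
            "variance_to_mean": "number"
          }
        },
        "discrepancy_D": "number",
        "negbin": {
          "type": "object",
          "required": { "mle": "any", "moments": "any" }
        },
        "gof": "any"
      }
    },
    "demography": {
      "type": "object",
      "required": {
        "rm": "number",
        "R0": "number",
        "T": "number",
        "DT": "number",
        "lam": "number",
        "life_table_ages": "number"
      }
    },
    "display": {
      "type": "object",
      "required": {
        "prevalence_pct": "number",
        "mean_intensity": "number",
        "mean_abundance": "number",
        "discrepancy_D": "number",
        "rm": "number",
        "R0": "number",
        "T": "number",
        "DT": "number"
      }
    }
  }
}
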