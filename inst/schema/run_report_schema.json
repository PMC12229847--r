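{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "metabhub run report",
  "type": "object",
  "required": ["counts", "signature", "thresholds"],
  "properties": {
    "counts": {
      "type": "object",
      "required": ["catalog", "selected", "network_nodes", "hubs"],
      "properties": {
        "catalog": {"type": "integer", "minimum": 0},
        "pass_trend": {"type": "integer", "minimum": 0},
        "pass_stage": {"type": "integer", "minimum": 0},
        "pass_survival": {"type": "integer", "minimum": 0},
        "selected": {"type": "integer", "minimum": 0},
        "network_nodes": {"type": "integer", "minimum": 0},
        "isolated": {"type": "integer", "minimum": 0},
        "hubs": {"type": "integer", "minimum": 0}
      }
    },
    "signature": {
      "type": "object",
      "required": ["up", "down"],
      "properties": {
        "up": {"type": "array", "items": {"type": "string"}},
        "down": {"type": "array", "items": {"type": "string"}}
      }
    },
    "scores": {
      "type": ["object", "null"],
      "properties": {
        "sample_id": {"type": "array", "items": {"type": "string"}},
        "score": {"type": "array", "items": {"type": "number"}},
        "group": {"type": "array", "items": {"type": "string"}}
      }
    },
    "survival": {
      "type": ["object", "null"],
      "properties": {
        "cutpoint": {"type": "number"},
        "chi2": {"type": "number"},
        "p": {"type": "number"},
        "n_low": {"type": "integer"},
        "n_high": {"type": "integer"},
        "direction": {"type": "string"}
      }
    },
    "gsea": {"type": ["object", "null"]},
    "methylation": {"type": ["object", "null"]},
    "thresholds": {
      "type": "object",
      "required": ["fdr", "surv_alpha", "rw_threshold"],
      "properties": {
        "fdr": {"type": "number"},
        "surv_alpha": {"type": "number"},
        "rw_threshold": {"type": "number"},
        "corr_threshold": {"type": "number"},
        "min_frac": {"type": "number"},
        "n_perm": {"type": "integer"},
        "seed": {"type": "integer"}
      }
    }
  }
}
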