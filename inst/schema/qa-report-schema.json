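{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "CT image-quality QA report",
  "type": "object",
  "required": ["provenance"],
  "properties": {
    "provenance": {
      "type": "object",
      "required": ["package_version", "seed", "metrics_requested"],
      "properties": {
        "package_version": {"type": "string"},
        "seed": {"type": "integer"},
        "metrics_requested": {"type": "array"},
        "inputs": {"type": "object"},
        "options": {"type": "object"}
      }
    },
    "mtf_wire": {
      "type": "object",
      "properties": {
        "f90": {"type": "number"}, "f50": {"type": "number"},
        "f10": {"type": "number"}, "f2": {"type": "number"}
      }
    },
    "mtf_edge": {
      "type": "object",
      "properties": {
        "f90": {"type": "number"}, "f50": {"type": "number"},
        "f10": {"type": "number"}, "f2": {"type": "number"}
      }
    },
    "ssp": {
      "type": "object",
      "required": ["fwhm_mm"],
      "properties": {"fwhm_mm": {"type": "number"}}
    },
    "nps": {
      "type": "object",
      "required": ["noise_sd", "peak_frequency"],
      "properties": {
        "noise_sd": {"type": "number"},
        "peak_frequency": {"type": "number"},
        "n_rois": {"type": "integer"},
        "peak_frequency_subtracted": {"type": "number"}
      }
    },
    "uniformity": {
      "type": "object",
      "required": ["centre_mean", "diffs", "limit", "pass"],
      "properties": {
        "centre_mean": {"type": "number"},
        "diffs": {"type": "object"},
        "limit": {"type": "number"},
        "pass": {"type": "boolean"}
      }
    },
    "hu": {"type": "array"},
    "lowcontrast": {
      "type": "object",
      "required": ["counts", "score", "rule_threshold"],
      "properties": {
        "counts": {"type": "object"},
        "score": {"type": "number"},
        "rule_threshold": {"type": "number"}
      }
    },
    "dosematch": {
      "type": "object",
      "required": ["reached"],
      "properties": {
        "matched_dose": {"type": "number"},
        "percent_increase": {"type": "number"},
        "reached": {"type": "boolean"}
      }
    }
  }
}
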