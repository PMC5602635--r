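{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "thrombovol pipeline report",
  "type": "object",
  "required": ["manifest", "monitor", "optical", "impedance", "comparison"],
  "properties": {
    "manifest": {
      "type": "object",
      "required": ["package", "version", "config_hash", "seed"],
      "properties": {
        "package": {"type": "string"},
        "version": {"type": "string"},
        "config_hash": {"type": "string"},
        "seed": {"type": "integer"},
        "created": {"type": "string"}
      }
    },
    "warnings": {"type": "array"},
    "monitor": {
      "type": "object",
      "properties": {
        "classification": {"type": "object"},
        "events": {"type": "array"},
        "baseline_ohm": {"type": "number"}
      }
    },
    "optical": {
      "type": "object",
      "properties": {
        "v_ot": {"type": "number"},
        "relative_uncertainty": {"type": "number"},
        "propagated_uncertainty": {"type": "number"},
        "threshold": {"type": "integer"},
        "h_zstack": {"type": "number"},
        "n_planes": {"type": "integer"}
      }
    },
    "impedance": {
      "type": "object",
      "properties": {
        "v_im": {"type": "number"},
        "relative_uncertainty": {"type": "number"},
        "scale_factor": {"type": "number"},
        "residual": {"type": "number"},
        "iterations": {"type": "integer"},
        "baseline_ohm": {"type": "number"},
        "z_measured": {"type": "number"},
        "saturation_fraction": {"type": "number"}
      }
    },
    "comparison": {
      "type": "object",
      "properties": {
        "v_ot": {"type": "number"},
        "v_im": {"type": "number"},
        "tolerance": {"type": "number"},
        "compatible": {"type": "boolean"}
      }
    }
  }
}
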