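{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "dcegkm analysis report",
  "type": "object",
  "required": ["input", "aif"],
  "properties": {
    "input": {
      "type": "object",
      "required": ["source", "n_frames", "dialect"],
      "properties": {
        "source": {"type": "string"},
        "n_frames": {"type": "integer", "minimum": 3},
        "dialect": {"enum": ["signal", "concentration"]}
      }
    },
    "aif": {
      "type": "object",
      "required": ["A1", "A2", "m1", "m2", "rss", "converged"],
      "properties": {
        "A1": {"type": "number"},
        "A2": {"type": "number"},
        "m1": {"type": "number", "exclusiveMinimum": 0},
        "m2": {"type": "number", "exclusiveMinimum": 0},
        "rss": {"type": "number", "minimum": 0},
        "converged": {"type": "boolean"}
      }
    },
    "gkm": {"$ref": "#/$defs/kinetic_fit"},
    "two_stage": {
      "type": "object",
      "required": ["split_min", "method", "stage2_mode",
                   "stage1", "stage2", "weighted_ve"],
      "properties": {
        "split_min": {"type": "number", "exclusiveMinimum": 0},
        "method": {"enum": ["fourier5", "linear", "nearest"]},
        "stage2_mode": {"enum": ["global_offset", "reorigin"]},
        "stage1": {"$ref": "#/$defs/kinetic_fit"},
        "stage2": {"$ref": "#/$defs/kinetic_fit"},
        "weighted_ve": {"type": "number"}
      }
    }
  },
  "oneOf": [{"required": ["gkm"]}, {"required": ["two_stage"]}],
  "$defs": {
    "kinetic_fit": {
      "type": "object",
      "required": ["Ktrans", "Kep", "rss", "converged"],
      "properties": {
        "Ktrans": {"type": "number", "minimum": 0},
        "Kep": {"type": "number", "minimum": 0},
        "ve": {"type": "number"},
        "rss": {"type": "number", "minimum": 0},
        "converged": {"type": "boolean"}
      }
    }
  }
}
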