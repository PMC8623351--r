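{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "tSCS calibration report",
  "type": "object",
  "required": ["rating", "thresholds", "rank_table", "cost_table",
               "recommendation", "invalid_cell_ratio"],
  "properties": {
    "rating": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["muscle", "electrode_position", "amplitude_mA",
                     "label", "color", "n_averaged"],
        "properties": {
          "muscle": {"type": "string"},
          "electrode_position": {"type": "integer"},
          "amplitude_mA": {"type": "number"},
          "label": {"type": "string",
                    "enum": ["no_response", "reflex", "m_wave", "invalid"]},
          "color": {"type": "string",
                    "enum": ["gray", "green", "yellow", "red"]},
          "amp1_uV": {"type": ["number", "null"]},
          "amp2_uV": {"type": ["number", "null"]},
          "suppression": {"type": ["number", "null"]},
          "n_averaged": {"type": "integer"}
        }
      }
    },
    "thresholds": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["electrode_position"],
        "properties": {
          "electrode_position": {"type": "integer"},
          "threshold_mA": {"type": ["number", "null"]}
        }
      }
    },
    "rank_table": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["rank", "electrode_position", "amplitude_mA",
                     "green_count"],
        "properties": {
          "rank": {"type": "integer"},
          "electrode_position": {"type": "integer"},
          "amplitude_mA": {"type": "number"},
          "green_count": {"type": "integer"},
          "delta_threshold_mA": {"type": "number"}
        }
      }
    },
    "cost_table": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["electrode_position", "amplitude_mA", "J"],
        "properties": {
          "electrode_position": {"type": "integer"},
          "amplitude_mA": {"type": "number"},
          "J": {"type": "number"}
        }
      }
    },
    "cost_normalizers": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["muscle", "max_amp1_uV"],
        "properties": {
          "muscle": {"type": "string"},
          "max_amp1_uV": {"type": "number"}
        }
      }
    },
    "recommendation": {
      "type": "object",
      "required": ["status"],
      "properties": {
        "status": {"type": "string", "enum": ["ok", "none"]},
        "reason": {"type": ["string", "null"]},
        "result": {
          "type": ["object", "null"],
          "properties": {
            "ranking": {
              "type": "object",
              "required": ["electrode_position", "threshold_mA",
                           "therapy_mA"],
              "properties": {
                "electrode_position": {"type": "integer"},
                "threshold_mA": {"type": "number"},
                "therapy_mA": {"type": "number"}
              }
            },
            "cost": {
              "type": "object",
              "required": ["electrode_position", "threshold_mA",
                           "therapy_mA", "J"],
              "properties": {
                "electrode_position": {"type": "integer"},
                "threshold_mA": {"type": "number"},
                "therapy_mA": {"type": "number"},
                "J": {"type": "number"}
              }
            },
            "agreement": {"type": "boolean"}
          }
        }
      }
    },
    "invalid_cell_ratio": {"type": "number"},
    "noise_profile": {
      "type": ["array", "null"],
      "items": {
        "type": "object",
        "required": ["muscle", "noise_uV"],
        "properties": {
          "muscle": {"type": "string"},
          "noise_uV": {"type": "number"}
        }
      }
    },
    "dispositions": {"type": ["array", "null"]}
  }
}
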