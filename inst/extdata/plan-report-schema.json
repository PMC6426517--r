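{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "fourfield plan report",
  "type": "object",
  "required": ["software", "patient_id", "prescription_gy", "config", "couch",
               "body", "isocenter", "landmarks", "apertures", "warnings"],
  "properties": {
    "software": {
      "type": "object",
      "required": ["name", "version"],
      "properties": {
        "name": {"type": "string"},
        "version": {"type": "string"}
      }
    },
    "patient_id": {"type": "string"},
    "prescription_gy": {"type": "number"},
    "fractions": {"type": "integer"},
    "config": {"type": "object"},
    "couch": {
      "type": "object",
      "required": ["found"],
      "properties": {
        "found": {"type": "boolean"},
        "peak_score": {"type": "number"}
      }
    },
    "body": {
      "type": "object",
      "required": ["voxel_count", "volume_cc"],
      "properties": {
        "voxel_count": {"type": "integer"},
        "volume_cc": {"type": "number"}
      }
    },
    "isocenter": {
      "type": "object",
      "required": ["position_mm", "residual_mm", "fiducials"],
      "properties": {
        "position_mm": {"type": "array"},
        "residual_mm": {"type": "number"},
        "fiducials": {"type": "array"}
      }
    },
    "landmarks": {
      "type": "object",
      "required": ["inlet_u_min", "inlet_u_max", "l4l5_v",
                   "obturator_inferior_v", "symphysis_anterior_u",
                   "sacrum_posterior_u"]
    },
    "apertures": {"type": "object"},
    "weights": {
      "type": "object",
      "required": ["optimized", "equal", "normalization"]
    },
    "metrics": {
      "type": "object",
      "required": ["optimized", "equal"]
    },
    "warnings": {"type": "array"},
    "timings_s": {"type": "object"}
  }
}
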