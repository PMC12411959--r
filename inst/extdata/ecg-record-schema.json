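{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Annotated ECG record (annotations.json)",
  "description": "Beat annotations accompanying signal.csv (columns sample_index,value). All segment index ranges are 0-based, half-open [onset, offset) sample indices into the signal. Segments must be sorted chronologically and non-overlapping, and every beat must carry exactly one QRS segment.",
  "type": "object",
  "required": ["patient_id", "record_id", "fs", "beats"],
  "properties": {
    "patient_id": { "type": "string" },
    "record_id": { "type": "string" },
    "fs": { "type": "number", "exclusiveMinimum": 0 },
    "beats": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["class", "segments"],
        "properties": {
          "class": { "enum": ["N", "S", "V"] },
          "segments": {
            "type": "object",
            "required": ["QRS"],
            "additionalProperties": false,
            "properties": {
              "P":   { "$ref": "#/definitions/range" },
              "QRS": { "$ref": "#/definitions/range" },
              "T":   { "$ref": "#/definitions/range" }
            }
          }
        }
      }
    }
  },
  "definitions": {
    "range": {
      "type": "array",
      "items": { "type": "integer", "minimum": 0 },
      "minItems": 2,
      "maxItems": 2,
      "description": "[onset, offset), onset < offset"
    }
  }
}
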