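{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "cardiosift run report",
  "type": "object",
  "required": ["timings", "detection", "selection", "balance", "metrics",
               "loss_curves", "config", "software"],
  "properties": {
    "timings": {"type": "object",
                "additionalProperties": {"type": "number", "minimum": 0}},
    "detection": {
      "type": "object",
      "required": ["n_detected", "n_beats_used"],
      "properties": {
        "n_detected": {"type": "integer", "minimum": 0},
        "n_annotated": {"type": "integer", "minimum": 0},
        "n_beats_used": {"type": "integer", "minimum": 0},
        "n_dropped": {"type": "integer", "minimum": 0}
      }
    },
    "selection": {"type": "object"},
    "balance": {"type": "object"},
    "metrics": {
      "type": "object",
      "required": ["accuracy", "precision", "recall", "f1", "confusion"],
      "properties": {
        "accuracy": {"type": "number", "minimum": 0, "maximum": 100},
        "precision": {"type": "number", "minimum": 0, "maximum": 100},
        "recall": {"type": "number", "minimum": 0, "maximum": 100},
        "f1": {"type": "number", "minimum": 0, "maximum": 100},
        "confusion": {"type": "array"}
      }
    },
    "loss_curves": {
      "type": "object",
      "required": ["train_loss"],
      "properties": {
        "train_loss": {"type": "array", "items": {"type": "number"}},
        "val_loss": {"type": ["array", "null"]}
      }
    },
    "config": {"type": "object"},
    "software": {"type": "string"}
  }
}
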