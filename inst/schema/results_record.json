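{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "fldpsim results record",
  "type": "object",
  "required": ["task", "algorithm", "model", "dp_enabled", "C", "eta",
               "seed", "accuracy", "macro_precision", "macro_recall",
               "macro_f1", "n_train", "n_test"],
  "properties": {
    "task": {"type": "string"},
    "algorithm": {"type": "string"},
    "model": {"type": "string"},
    "dp_enabled": {"type": "boolean"},
    "C": {"type": "number"},
    "eta": {"type": "number"},
    "seed": {"type": "number"},
    "accuracy": {"type": "number"},
    "macro_precision": {"type": "number"},
    "macro_recall": {"type": "number"},
    "macro_f1": {"type": "number"},
    "eps_basic": {"type": "number"},
    "eps_sublinear": {"type": "number"},
    "n_train": {"type": "number"},
    "n_test": {"type": "number"},
    "error": {"type": "string"}
  }
}
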