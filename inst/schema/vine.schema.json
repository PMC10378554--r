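{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "C-vine copula fit",
  "description": "Serialized structure of a fitted C-vine: root ordering, per-edge records and independence-test results. Density grids live in a separate archive keyed by edge index.",
  "type": "object",
  "required": ["d", "n", "alpha", "estimator", "grid_size", "order", "labels", "edges"],
  "properties": {
    "d": {"type": "integer", "minimum": 2},
    "n": {"type": "integer", "minimum": 2},
    "alpha": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1},
    "estimator": {"enum": ["fallback", "flow"]},
    "grid_size": {"type": "integer", "minimum": 2},
    "order": {
      "type": "array",
      "items": {"type": "integer"},
      "description": "root sequence: permutation of 1..d by descending Kendall tau sums"
    },
    "labels": {"type": "array", "items": {"type": "string"}},
    "edges": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["index", "tree", "root", "partner", "conditioning", "independent", "label"],
        "properties": {
          "index": {"type": "integer", "minimum": 1},
          "tree": {"type": "integer", "minimum": 1},
          "root": {"type": "integer", "description": "original column index of the tree-t hub variable"},
          "partner": {"type": "integer", "description": "original column index of the partner variable"},
          "conditioning": {"type": "array", "items": {"type": "integer"}},
          "p_value": {"type": ["number", "null"]},
          "independent": {"type": "boolean"},
          "label": {"type": "string", "description": "e.g. \"v3,v7|v1,v2\""}
        }
      }
    }
  }
}
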