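{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "mespool pooling trace",
  "type": "object",
  "required": ["format", "version", "smiles", "n_atoms", "layers"],
  "properties": {
    "format": {"const": "mespool_pooling_trace"},
    "version": {"type": "integer"},
    "smiles": {"type": "string"},
    "n_atoms": {"type": "integer", "minimum": 1},
    "layers": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["groups", "new_groups", "preserved_bonds"],
        "properties": {
          "groups": {
            "description": "partition of 1..n_atoms into current nodes",
            "type": "array",
            "items": {"type": "array", "items": {"type": "integer", "minimum": 1}}
          },
          "new_groups": {
            "description": "atom subsets contracted at this layer (reduction stage)",
            "type": "array",
            "items": {"type": "array", "items": {"type": "integer", "minimum": 1}}
          },
          "preserved_bonds": {
            "description": "surviving bonds as original atom pairs (connection stage)",
            "type": "array",
            "items": {
              "type": "array",
              "items": {"type": "integer", "minimum": 1},
              "minItems": 2,
              "maxItems": 2
            }
          }
        }
      }
    }
  }
}
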