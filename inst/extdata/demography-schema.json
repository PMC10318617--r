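{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "imcoal demography configuration",
  "description": "Rooted binary population tree in mutation-scaled units: theta = 4*Ne*mu per branch, tau (expected substitutions per site) per internal node, directed migration bands with rate m = per-generation migration probability / mu. Written canonically (sorted keys) by saveDemography().",
  "type": "object",
  "required": ["populations", "edges", "theta", "tau"],
  "properties": {
    "populations": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "tip"],
        "properties": {
          "id": {"type": "string"},
          "name": {"type": "string"},
          "tip": {"type": "boolean"}
        }
      }
    },
    "edges": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["child", "parent"],
        "properties": {
          "child": {"type": "string"},
          "parent": {"type": "string"}
        }
      }
    },
    "theta": {
      "type": "object",
      "description": "node id -> theta; one strictly positive entry per node",
      "additionalProperties": {"type": "number", "exclusiveMinimum": 0}
    },
    "tau": {
      "type": "object",
      "description": "internal node id -> tau; parents strictly older than children; tips are implicitly 0",
      "additionalProperties": {"type": "number", "exclusiveMinimum": 0}
    },
    "migration_bands": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["source", "target", "rate"],
        "properties": {
          "id": {"type": "string"},
          "source": {"type": "string", "description": "forward-time donor population"},
          "target": {"type": "string", "description": "forward-time recipient population"},
          "rate": {"type": "number", "minimum": 0},
          "pair": {"type": ["string", "null"], "description": "shared id linking the two directions of a bidirectional band"}
        }
      }
    }
  }
}
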