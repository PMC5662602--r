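{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "fbagea constraint-based model (COBRA JSON subset)",
  "type": "object",
  "required": ["metabolites", "reactions", "genes", "biomass_reaction_id"],
  "properties": {
    "id": {"type": "string"},
    "metabolites": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id"],
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "name": {"type": "string"},
          "compartment": {"type": "string"}
        }
      }
    },
    "reactions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "stoichiometry"],
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "name": {"type": "string"},
          "stoichiometry": {
            "type": "object",
            "description": "metabolite id -> signed coefficient; numbers, decimal strings or exact fractions 'p/q'. Substrates negative, products positive.",
            "additionalProperties": {
              "anyOf": [
                {"type": "number"},
                {"type": "string", "pattern": "^[+-]?[0-9]+(/[0-9]+|\\.[0-9]+)?$"}
              ]
            }
          },
          "lower_bound": {"type": "number"},
          "upper_bound": {"type": "number"},
          "reversible": {"type": "boolean"},
          "gpr": {
            "type": "string",
            "description": "boolean gene rule: gene ids, parentheses, 'and', 'or' (case-insensitive); empty string = no gene association"
          },
          "is_exchange": {"type": "boolean"}
        }
      }
    },
    "genes": {"type": "array", "items": {"type": "string"}},
    "biomass_reaction_id": {"type": "string"},
    "medium": {
      "type": "object",
      "description": "exchange reaction id -> maximum intake flux (mmol/gDW/h, nonnegative); uptake itself is carried as negative flux through the exchange",
      "additionalProperties": {"type": "number", "minimum": 0}
    }
  }
}
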