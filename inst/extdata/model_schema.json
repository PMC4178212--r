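{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "fluxcue metabolic model dialect",
  "description": "A stoichiometric metabolic network with flux bounds, gene-protein-reaction rules and pathway labels. Record order is significant and preserved by the reader.",
  "type": "object",
  "required": ["metabolites", "reactions"],
  "properties": {
    "metabolites": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id"],
        "properties": {
          "id": {"type": "string", "minLength": 1, "description": "unique metabolite identifier"},
          "name": {"type": "string", "description": "free-text name; defaults to id"},
          "compartment": {"type": "string", "minLength": 1, "description": "compartment tag, e.g. 'c' (cytosol), 'er' (endoplasmic reticulum); defaults to 'c'"}
        }
      }
    },
    "reactions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "stoich"],
        "properties": {
          "id": {"type": "string", "minLength": 1, "description": "unique reaction identifier"},
          "stoich": {
            "type": "object",
            "minProperties": 1,
            "additionalProperties": {"type": "number"},
            "description": "metabolite id -> signed coefficient; negative = consumed. Exchange reactions are one-sided."
          },
          "lb": {"type": "number", "description": "lower flux bound; default -1000 if reversible is true, else 0"},
          "ub": {"type": "number", "description": "upper flux bound; default 1000"},
          "reversible": {"type": "boolean", "description": "only consulted for defaulting bounds; the canonical reversibility is lb < 0"},
          "gpr": {"type": "string", "description": "boolean gene rule, identifiers with 'and'/'or' and parentheses, case-insensitive; empty = no gene association"},
          "pathway": {"type": "string", "description": "subsystem label; empty = unannotated"},
          "exchange": {"type": "boolean", "description": "true for one-sided boundary reactions", "default": false}
        }
      }
    }
  }
}
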