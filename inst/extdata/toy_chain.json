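{
  "metabolites": [
    {"id": "A", "name": "metabolite A", "compartment": "c"},
    {"id": "B", "name": "metabolite B", "compartment": "c"},
    {"id": "C", "name": "metabolite C", "compartment": "c"}
  ],
  "reactions": [
    {"id": "R1", "stoich": {"A": 1}, "lb": 0, "ub": 10, "gpr": "", "pathway": "", "exchange": true},
    {"id": "R2", "stoich": {"A": -1, "B": 1}, "lb": 0, "ub": 10, "gpr": "g2", "pathway": "chain", "exchange": false},
    {"id": "R3", "stoich": {"B": -1, "C": 1}, "lb": 0, "ub": 10, "gpr": "g3", "pathway": "chain", "exchange": false},
    {"id": "R4", "stoich": {"C": -1}, "lb": 0, "ub": 10, "gpr": "", "pathway": "", "exchange": true}
  ]
}
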