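{
  "id": "mini",
  "metabolites": [
    {
      "id": "a_e",
      "compartment": "e"
    },
    {
      "id": "a_c",
      "compartment": "c"
    }
  ],
  "reactions": [
    {
      "id": "EX_a",
      "name": "EX_a",
      "metabolites": {
        "a_e": -1
      },
      "lower_bound": -10,
      "upper_bound": 0,
      "gene_reaction_rule": "",
      "subsystem": "",
      "objective_coefficient": 0
    },
    {
      "id": "At",
      "name": "At",
      "metabolites": {
        "a_e": -1,
        "a_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 10,
      "gene_reaction_rule": "gT1 or gT2",
      "subsystem": "",
      "objective_coefficient": 0
    },
    {
      "id": "DM_a",
      "name": "DM_a",
      "metabolites": {
        "a_c": -1
      },
      "lower_bound": 0,
      "upper_bound": 10,
      "gene_reaction_rule": "",
      "subsystem": "",
      "objective_coefficient": 1
    }
  ],
  "genes": [
    {
      "id": "gT1"
    },
    {
      "id": "gT2"
    }
  ]
}
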