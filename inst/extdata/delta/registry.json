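[
  {
    "name": "OrganismMapper",
    "inputs": [
      "gene"
    ],
    "output": "organism",
    "mode": "mock",
    "table": "OrganismMapper.tsv"
  },
  {
    "name": "IDMapper",
    "inputs": [
      "gene",
      "gene"
    ],
    "output": "relationship",
    "mode": "mock",
    "table": "IDMapper.tsv"
  },
  {
    "name": "GeneMapper",
    "inputs": [
      "gene name"
    ],
    "output": "gene",
    "mode": "mock",
    "table": "GeneMapper.tsv"
  },
  {
    "name": "GeneCards",
    "inputs": [
      "gene name"
    ],
    "output": "gene",
    "mode": "live"
  }
]
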