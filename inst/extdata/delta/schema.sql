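CREATE TABLE Gene (
  GeneName TEXT,
  GeneID TEXT,
  UniProtID TEXT,
  DNASequence TEXT,
  Organism TEXT,
  PRIMARY KEY (GeneID)
);

CREATE TABLE Protein (
  ProteinName TEXT,
  ProteinID TEXT,
  Function TEXT,
  PRIMARY KEY (ProteinID)
);

CREATE TABLE EquivalentGenes (
  Object1 TEXT,
  Object2 TEXT,
  Relationship TEXT,
  PRIMARY KEY (Object1, Object2)
);

CREATE TABLE GeneProteinEncoding (
  Gene TEXT,
  Protein TEXT,
  PRIMARY KEY (Gene, Protein)
);
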