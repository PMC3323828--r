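"ProteinName","ProteinID","Function"
"Ubiquinol-cytochrome c reductase complex chaperone","Q9NVA1","growth control"
"Cytochrome b-c1 complex subunit 7","Q0MQ57","electron transport"
"Ubiquinol-cytochrome c reductase chaperone homolog","E2RFK3","growth control"
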