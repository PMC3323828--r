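"GeneName","GeneID","UniProtID","DNASequence","Organism"
"UQCC","55245","Q9NVA1","ATGGCTGCTCGGCTGCTGCGGGCTGTGATCGGCGCTCTGA","Human"
"LOC458201","458201","Q0MQ57","ATGGCTGCTCGGCTGCTGCGGGCTGTGATCGGCGCTCTCA","Chimpanzee"
"LOC608882","LOC608882","E2RFK3","ATGGATGCTCGGCTGCTGCGGGCTGTGATCGGCGCTCTCA","Dog"
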