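surface	lemma	pos	type	canonical
human	human	noun	organism	Human
humans	human	noun	organism	Human
dog	dog	noun	organism	Dog
dogs	dog	noun	organism	Dog
chimpanzee	chimpanzee	noun	organism	Chimpanzee
chimpanzees	chimpanzee	noun	organism	Chimpanzee
plant	plant	noun	organism	Plant
growth control	growth control	NA	function	growth control
electron transport	electron transport	NA	function	electron transport
ortholog	ortholog	noun	relationship	Ortholog
orthologs	ortholog	noun	relationship	Ortholog
homolog	homolog	noun	relationship	Homolog
homologs	homolog	noun	relationship	Homolog
ubiquinol-cytochrome c reductase complex chaperone	ubiquinol-cytochrome c reductase complex chaperone	NA	protein name	NA
cytochrome b-c1 complex subunit 7	cytochrome b-c1 complex subunit 7	NA	protein name	NA
ubiquinol-cytochrome c reductase chaperone homolog	ubiquinol-cytochrome c reductase chaperone homolog	NA	protein name	NA
gene	gene	noun	NA	NA
genes	gene	noun	NA	NA
protein	protein	noun	NA	NA
proteins	protein	noun	NA	NA
organism	organism	noun	NA	NA
organisms	organism	noun	NA	NA
function	function	noun	NA	NA
functions	function	noun	NA	NA
sequence	sequence	noun	NA	NA
sequences	sequence	noun	NA	NA
growth	growth	noun	NA	NA
control	control	noun	NA	NA
list	list	verb	NA	NA
print	print	verb	NA	NA
return	return	verb	NA	NA
show	show	verb	NA	NA
find	find	verb	NA	NA
encode	encode	verb	NA	NA
encodes	encode	verb	NA	NA
encoded	encode	verb	NA	NA
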