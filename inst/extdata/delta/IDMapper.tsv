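id1	id2	relationship
UQCC	LOC608882	Ortholog
UQCC	LOC458201	Ortholog
55245	LOC608882	Ortholog
55245	LOC458201	Ortholog
LOC608882	UQCC	Ortholog
LOC458201	UQCC	Ortholog
LOC608882	55245	Ortholog
LOC458201	55245	Ortholog
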