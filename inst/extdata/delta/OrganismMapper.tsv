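id	organism
55245	Human
458201	Chimpanzee
LOC608882	Dog
UQCC	Human
LOC458201	Chimpanzee
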