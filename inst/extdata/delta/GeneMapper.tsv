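name	id
UQCC	55245
LOC458201	458201
LOC608882	LOC608882
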