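"Object1","Object2","Relationship"
"UQCC","LOC608882","Ortholog"
"UQCC","LOC458201","Ortholog"
"55245","LOC608882","Ortholog"
"55245","LOC458201","Ortholog"
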