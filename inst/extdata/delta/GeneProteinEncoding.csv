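"Gene","Protein"
"55245","Q9NVA1"
"458201","Q0MQ57"
"LOC608882","E2RFK3"
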