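db_ddl: schema.sql
db_data: "."
ontology: ontology.yaml
lexicon: lexicon.tsv
registry: registry.json
max_depth: 2
sample_size: 100
seed: 1
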