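concepts:
- name: gene
  type: gene
- name: protein
  type: protein
- name: organism
  type: organism
- name: function
  type: function
associations:
- name: partof
  source: gene
  target: organism
- name: has
  source: gene
  target: function
- name: encode
  source: gene
  target: protein
- name: alias
  source: gene
  target: gene
- name: function
  source: protein
  target: function
types:
  root: entity
  edges:
  - - identifier
    - entity
  - - gene
    - identifier
  - - gene name
    - gene
  - - protein
    - identifier
  - - name
    - entity
  - - protein name
    - name
  - - organism
    - entity
  - - plant
    - organism
  - - function
    - entity
  - - molecular function
    - function
  - - biological process
    - function
  - - sequence
    - entity
  - - relationship
    - entity
rules:
- function(X, Y) <- alias(X, Z), has(Z, Y)
- alias(X, Y) <- homolog(X, Y)
- alias(X, Y) <- ortholog(X, Y)
- alias(X, Y) <- gene(X), encode(X, Y)
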