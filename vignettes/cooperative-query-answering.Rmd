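---
title: "Cooperative natural-language query answering over relational biological databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooperative natural-language query answering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopquery)
```

## The problem

Biological databases answer questions their schema anticipated. A
biologist asking *"List all growth control genes in dogs"* does not care
that gene function lives in a `Protein` table reachable only through a
UniProt accession, or that the dog gene may be recorded only as an
ortholog of a human gene. `coopquery` is a semantic layer between short
English questions and an arbitrary relational schema: it translates a
question into a union of SQL queries, including *intensional* branches
that derive answers through inference rules and external lookup
functions when no stored row answers the question directly
(cooperative query answering).

The pipeline has three stages, each exposed as ordinary functions so any
stage can be inspected or replaced:

1. **Term analyzer** — `parse_query()` + `match_terms()`: tokenize,
   lemmatize and role-label the question, then bind head nouns,
   modifiers, proper nouns and transitive verbs to schema-graph nodes.
2. **Semantic graph matcher** — `connect_matches()` +
   `attach_constraints()`: connect the bound nodes into a *logical query
   graph*, a connected subgraph of the schema graph, and attach the
   selection literals.
3. **Query generator** — `expand_derivations()` + `generate_sql()` +
   `execute_sql()`: rewrite the query with the ontology's Horn rules,
   ground every derivation into a SQL branch, and evaluate the union
   read-only with per-row provenance.

## The schema graph

The database-independence of the approach rests on one structure built
by `build_schema_graph()`. Its inputs are a relational instance with
declared keys (3NF is assumed), an ontology `O = (C, R, I, T)` —
concepts, binary associations, inference rules, and a type hierarchy —
and a registry of typed external functions. Construction proceeds in
five steps:

1. **Column typing.** Up to `sample_size` (default 100) distinct values
   per column are typed by a lexicon plus syntactic shape rules (an
   all-digit token types as a gene identifier, a UniProt-shaped
   accession as a protein, an ACGT string as a sequence, a short symbol
   as a gene name). The column's type is the least upper bound
   (`type_lub()`) of its sampled value types; untypable columns get the
   hierarchy root. The sample is deterministic under a seed, so graph
   construction is reproducible bit for bit.
2. **Concept mapping (μ).** A column is assigned to the most specific
   concept whose type node subsumes the column type; ties break
   lexicographically and are logged. Assignments are globally
   injective: no column belongs to two concepts. Within one relation,
   when several columns carry the same concept the mapping keeps the key
   column (else the first in schema order): two same-concept columns in
   one relation represent a *relationship between* objects of that
   concept, not two independent representations, so the second prime
   column is recorded as the association's partner column (this is how
   `alias` finds `⟨Object1, Object2⟩` in the equivalence table) and
   non-key duplicates are demoted to unnamed properties. A concept whose
   column is by itself a primary key is *entity-mapped*; other mappings
   are *property* mappings.
3. **Relationship mapping.** An association `a(c, c′)` maps either to a
   prime-attribute pair of a relationship relation (key–key, both
   endpoints entity-mapped elsewhere) or to a key plus a property column
   of the same relation (key–property). Associations with no satisfying
   pair are recorded as unmapped, never dropped — in the bundled world
   `has(gene, function)` is unmapped extensionally and only reachable
   through the graph.
4. **Value mapping (φ).** Concepts with no column home — including
   predicates that appear only in rules, which the ontology explicitly
   permits — are scanned against instance values (case-insensitive exact
   match plus lexicon synonyms). A hit in a relation that carries a
   key–key association is anchored as a relationship triple
   (`ortholog ↣ ⟨Object1, Object2, Relationship⟩`); a hit elsewhere is
   anchored to the relation's key. Concepts matching nothing are flagged
   function-resolvable.
5. **Backward mapping.** Columns the ontology does not cover still get
   nodes: each spawns a database-derived concept (named after the
   column) with an unnamed property edge to its relation's key, so users
   may query in database vocabulary the ontology never mentions.

Nodes are concepts, columns and functions; edges are classifications,
named associations, unnamed properties and function wiring. All edges
weigh 1 except function wiring (weight 2), so when a stored join path
and a computed path tie, the stored one wins — cooperation re-adds
function branches through rules rather than through path search.

```{r}
w <- build_delta()
sg <- build_schema_graph(w$db, w$ontology, w$registry, w$lexicon)
glance(sg)
```

## Query translation

`parse_query()` is a deliberately small deterministic parser: leading
"List/Print/Return" marks an imperative, "Does/Is" an existential
question answered by a boolean, "What/Which" an interrogative.
Contiguous noun runs become semantic roles (last common noun is the
head, the rest are modifiers); a preposition opens a new role. A real
dependency parser can be substituted through the `parser` argument of
`ask()` — the pipeline only needs tokens, roles and verbs — but the
bundled fallback keeps the test suite free of heavyweight models, and
the approach deliberately stays uncommitted to one parser.

`match_terms()` applies the part-of-speech correspondence: common nouns
bind to concepts, proper nouns and quoted tokens to stored values
(producing selection literals), transitive verbs to association names,
modifier runs first to one multiword value literal ("growth control")
and only then token by token. Two details matter for cooperation:

* a term may match several columns (55245 is stored in three
  relations); all candidates are kept and the connector picks the one
  nearest the primary terminal, ties lexicographic;
* when a lexicon entry knows a term's canonical value and type but no
  stored row carries the value (ask for dogs after the dog row was
  deleted), the literal is still anchored to same-typed columns — the
  answer may be derivable even though the direct selection is empty.

Adverbs would map to association properties in the correspondence; the
schema graph has no association-property store, so adverb matches are
logged and ignored during SQL generation.

`connect_matches()` runs a deterministic shortest-path search (unit
weights, lexicographic tie-break on node IDs; terminals beyond the
second are merged Steiner-style in descending match-score order). A
match whose terminals sit in different components is *rejected* with a
diagnostic naming the stranded terminals — only a connected match is
accepted as a logical query graph. On the bundled world the
growth-control question connects along

```
gene — Gene.GeneID — Gene.UniProtID — protein — Protein.ProteinID — Protein.Function
```

which already encodes the join the printed SQL needs, including the
UniProtID/ProteinID correspondence that is nowhere declared as a foreign
key: it emerges from both columns typing as proteins.

## Cooperative expansion and SQL generation

The accepted graph is converted to a conjunctive form: the answer
variable carries the head concept, each selection becomes an association
atom `partof(X, 'Dog')`, `function(X, 'growth control')`, and verbs
become association atoms between role variables.
`expand_derivations()` then performs standard Datalog unfolding: an atom
whose predicate heads a rule is replaced by the rule body with fresh
variables, breadth-first to `max_depth`, duplicates removed modulo
renaming. The default depth 2 reaches every chain the bundled rules
need (`function ← alias ← ortholog`); expansion terminates at the bound
for any rule set, recursive or not.

Grounding a derivation walks the schema graph: column-to-column hops
inside a relation stay in one table instance, concept crossings become
equality joins, value-mapped predicates open the relationship relation
with its discriminator value (`Relationship = 'Ortholog'`, tried in both
argument orders because the table stores an equivalence relation), and
atoms whose object concept is produced by a registered function emit the
cooperative variant `OrganismMapper(X) = 'Dog'` as an extra branch.
Variables left without a table column get a domain table when their
concept is entity-mapped (Datalog safety); underivable branches are
dropped and recorded. Functions run as engine-registered scalar calls —
observably equivalent to treating them as tables, with far simpler
machinery. Mock implementations back onto bundled lookup tables; live
entries (a GeneCards stub ships as an example) keep the same contract
but refuse to run, so no test ever touches the network. Sequence
homology is a registered check with threshold θ = 0.9 on a plain
identity fraction; no reference value for θ exists, so it is an explicit,
documented placeholder.

```{r}
ans <- ask(w, "List all growth control genes in dogs", sg = sg)
tidy(ans)
cat(ans$sql$branches$sql[1], sep = "\n")
```

The union is evaluated branch by branch, read-only, each answer row
carrying the set of derivations that produced it. Deleting the Gene row
that answers the dogs question directly leaves the unioned answer
unchanged — the ortholog join plus organism-mapper branch still derives
it:

```{r}
db2 <- w$db
db2$tables$Gene <- db2$tables$Gene[db2$tables$Gene$GeneID != "LOC608882", ]
ask(db2, "List all growth control genes in dogs", ontology = w$ontology,
    lexicon = w$lexicon, registry = w$registry)$rows
```

## The bundled example world and the random generator

`build_delta()` ships the worked world: a human gene (symbol UQCC, ID
55245) encoding the growth-control protein Q9NVA1, its chimpanzee
(LOC458201) and dog (LOC608882) orthologs in an `EquivalentGenes`
relation, and a `GeneProteinEncoding` relation. Only these stated facts
are treated as ground truth; sequences, protein names and remaining
cells are synthetic, type-conformant filler. The equivalence table
carries the ortholog facts both in symbol vocabulary (UQCC) and in
identifier vocabulary (55245) — symbol/identifier equivalence is itself
one of the modeled knowledge rules, and the identifier-level row is what
lets the expanded SQL join `G.GeneID = E.Object1` directly. The
resilience experiment deletes the LOC608882 row, the one whose absence
the cooperative union must survive.

`random_world()` generates property-test worlds: a random multi-relation
schema with declared keys, a flat type tree, and instances whose values
carry explicit `type::value` tags so column typing is exact; one concept
is always entity-mapped and one is always planted as a value concept.
It emulates the *structural* variety of schemas (key shapes, column
types, association placement), not realistic data: passing the property
suites shows the mapping and connection machinery is sound on arbitrary
3NF-style schemas, and says nothing about parsing accuracy on free text
or about noisy, partially typed real columns. Problem sizes are kept at
desk scale throughout — worlds of up to five relations, graphs of a few
dozen nodes, 200-world sweeps — which exercises every code path in
seconds.

## Numerical and design choices

* **Determinism everywhere.** Ties are never left to hash or platform
  order: least-upper-bound ties, concept-assignment ties, path ties and
  candidate-anchor ties all break lexicographically (radix order) and
  are logged under `options(coopquery.verbose = TRUE)`. Two runs with
  the same inputs and seed are byte-identical, which the tests assert.
* **Projection of expanded branches.** A branch projects the answer
  variable's representative column. For the ortholog branch that is
  `E.Object2`, the ortholog partner — projecting the gene that answers
  the question rather than the gene that carried the evidence. This is
  the semantically coherent reading of the derivation and what makes the
  resilience answer come out right.
* **Composite keys.** "Prime attribute" is read as membership in the
  declared primary key; foreign keys are neither required nor used —
  join paths come from type-compatible mappings, not metadata.
* **Value-literal comparison** is case-insensitive end to end (matcher
  and evaluator agree), and the stored capitalization is what appears in
  emitted SQL (`'Dog'`, `'growth control'`).
* **Degenerate inputs.** Empty ontologies yield a backward-mapped graph;
  empty columns type as the root; queries with no groundable content
  word, or with stranded terminals, fail with classed conditions
  (`coopquery_no_match_error`, `coopquery_disconnected_error`) that the
  command-line wrapper maps to exit code 3.

## Limitations

The fallback parser covers short imperative, existential and simple
interrogative questions; long relative-clause queries (and negation,
e.g. "but are absent in fruit flies") are out of scope — published
dependency parsers also degrade there, which is why the parser seat is
pluggable. "Why/How" questions require deductive explanation and are
not attempted. SQL generation covers select/join/selection unions with
scalar function calls; aggregates and grouping are not generated. Rule
expansion is bounded unfolding, not full recursive Datalog evaluation,
so answers requiring unbounded recursion depth are only found up to
`max_depth`.
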