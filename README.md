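# coopquery

Cooperative natural-language query answering over relational biological
databases.

Biologists ask questions like *"List all growth control genes in dogs"*;
relational databases answer SQL. Worse, in biology the answer often is
not stored at all — it is *derivable*: the dog gene may be recorded only
as an ortholog of a human gene whose protein's function is known.
`coopquery` is a database-independent semantic layer that translates
short English questions into unions of SQL queries, including branches
that reach answers through inference rules and external lookup functions
(identifier mappers, organism mappers, sequence-homology checks). When a
ground row is missing, the union still returns the derivable answer —
*cooperative* query answering.

## The method

Three components sit between the question and the database:

1. **Schema graph.** An ontology `O = (C, R, I, T)` — concepts, binary
   associations, Horn-style inference rules such as
   `function(X, Y) <- alias(X, Z), has(Z, Y)` and
   `alias(X, Y) <- ortholog(X, Y)`, plus a type hierarchy — is merged
   with the database scheme. Column values are sampled and typed; each
   column's type is the least upper bound of its value types; concepts
   map injectively to columns (`μ(gene) = {Gene.GeneID,
   EquivalentGenes.Object1, GeneProteinEncoding.Gene}`), associations map
   to column pairs (`alias ⇁ ⟨Object1, Object2⟩`,
   `partof ⇁ ⟨GeneID, Organism⟩`), concepts without a column home map to
   stored values (`ortholog` as `Relationship = 'Ortholog'`), and
   uncovered columns are backward-mapped into database-derived concepts.
   External functions join the graph as typed nodes.
2. **Term analyzer + graph matcher.** Head nouns bind to concepts,
   proper nouns and modifier phrases to stored values, transitive verbs
   to associations; the bound nodes are connected by deterministic
   shortest-path/Steiner search into a *logical query graph* — a
   connected subgraph of the schema graph. Disconnected matches are
   rejected with a diagnostic.
3. **Query generator.** Datalog-style unfolding of the ontology rules
   produces alternative derivations; each grounds into a SQL branch
   (joins from graph walks, selections from value literals, registered
   scalar functions in WHERE); the branches are deduplicated, unioned,
   and evaluated read-only with per-row provenance.

## Worked example

The package ships the worked world (`build_delta()`): a human gene UQCC
(ID 55245) encoding the growth-control protein Q9NVA1, with chimpanzee
(LOC458201) and dog (LOC608882) orthologs recorded in an
`EquivalentGenes` relation, plus mock OrganismMapper / IDMapper /
GeneMapper / sequence-homology functions.

```r
library(coopquery)

w  <- build_delta()
sg <- build_schema_graph(w$db, w$ontology, w$registry, w$lexicon)

ans <- ask(w, "List all growth control genes in dogs", sg = sg)
ans
#> <coop_answer> "List all growth control genes in dogs"
#>   5 derivation(s), 10 SQL branch(es)
#> # A tibble: 1 × 2
#>   GeneID    provenance
#>   <chr>     <list>
#> 1 LOC608882 <chr [3]>
```

The single answer LOC608882 is supported by three derivations: the
direct organism lookup, the ortholog route through `EquivalentGenes`,
and the gene-encodes-protein route. The base branch is exactly the
join-plus-selection SQL a practitioner would write by hand:

```r
cat(ans$sql$branches$sql[1])
#> select G.GeneID from Gene G, Protein P
#>   where G.Organism = 'Dog' and G.UniProtID = P.ProteinID
#>   and P.Function = 'growth control'
```

while the cooperative branch that survives deletion of the dog's own
Gene row reads

```
select E.Object2 from EquivalentGenes E, Gene G, Protein P
  where OrganismMapper(E.Object2) = 'Dog' and E.Relationship = 'Ortholog'
  and E.Object1 = G.GeneID and G.UniProtID = P.ProteinID
  and P.Function = 'growth control'
```

Existential questions return a boolean (`ask(w, "Does gene 55245 encode
a protein")` is `TRUE`), and `tidy()` / `glance()` give flat summaries:

```r
tidy(ans)
#> # A tibble: 1 × 2
#>   GeneID    provenance
#>   <chr>     <chr>
#> 1 LOC608882 d1+d4+d5
```

A thin command-line wrapper covers the same pipeline
(`inst/scripts/coopquery.R` with subcommands `build-graph`, `ask`,
`expand`, `validate-fixtures`; exit codes 0/2/3/4 for
success/usage/grounding failure/construction failure), driven by the
bundled config in `inst/extdata/delta/`.

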