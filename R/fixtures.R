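#' The worked gene/protein/ortholog example world
#'
#' Builds the four-relation example database (genes with identifiers,
#' UniProt accessions, DNA sequences and organisms; proteins with
#' functions; an equivalence relation between gene products; a
#' gene-protein encoding relation), the matching ontology (concepts gene,
#' protein, organism, function; associations partof, has, encode, alias,
#' function; rules deriving gene function through aliases, orthologs,
#' homologs and encodings), a term lexicon, and a registry of mock
#' external functions (OrganismMapper, IDMapper, GeneMapper, a
#' sequence-identity Homolog check, and a disabled live GeneCards entry).
#'
#' Facts the worked examples rely on: gene 55245 (symbol UQCC, human)
#' encodes the growth-control protein Q9NVA1; UQCC is an ortholog of the
#' dog gene LOC608882 and of the chimpanzee gene LOC458201; LOC608882's
#' organism is Dog.  All other cells (sequences, extra names) are
#' synthetic type-conformant filler.
#'
#' @param homology_threshold identity fraction above which the Homolog
#'   mock reports two genes homologous.
#' @return a list of class `coop_world` with elements `db`, `ontology`,
#'   `lexicon`, `registry`.
#' @examples
#' w <- build_delta()
#' w$db
#' @export
build_delta <- function(homology_threshold = 0.9) {
  seq_h <- "ATGGCTGCTCGGCTGCTGCGGGCTGTGATCGGCGCTCTGA"
  seq_c <- sub("TGA$", "TCA", seq_h)                 # 1 mismatch vs human
  seq_d <- sub("^ATGGC", "ATGGA", sub("TGA$", "TCA", seq_h))  # 2 mismatches

  gene <- tibble(
    GeneName = c("UQCC", "LOC458201", "LOC608882"),
    GeneID = c("55245", "458201", "LOC608882"),
    UniProtID = c("Q9NVA1", "Q0MQ57", "E2RFK3"),
    DNASequence = c(seq_h, seq_c, seq_d),
    Organism = c("Human", "Chimpanzee", "Dog"))
  protein <- tibble(
    ProteinName = c("Ubiquinol-cytochrome c reductase complex chaperone",
                    "Cytochrome b-c1 complex subunit 7",
                    "Ubiquinol-cytochrome c reductase chaperone homolog"),
    ProteinID = c("Q9NVA1", "Q0MQ57", "E2RFK3"),
    Function = c("growth control", "electron transport", "growth control"))
  equivalent <- tibble(
    Object1 = c("UQCC", "UQCC", "55245", "55245"),
    Object2 = c("LOC608882", "LOC458201", "LOC608882", "LOC458201"),
    Relationship = c("Ortholog", "Ortholog", "Ortholog", "Ortholog"))
  encoding <- tibble(
    Gene = c("55245", "458201", "LOC608882"),
    Protein = c("Q9NVA1", "Q0MQ57", "E2RFK3"))

  db <- database(
    schemas = list(
      relation_schema("Gene",
                      c("GeneName", "GeneID", "UniProtID", "DNASequence", "Organism"),
                      key = "GeneID"),
      relation_schema("Protein", c("ProteinName", "ProteinID", "Function"),
                      key = "ProteinID"),
      relation_schema("EquivalentGenes", c("Object1", "Object2", "Relationship"),
                      key = c("Object1", "Object2")),
      relation_schema("GeneProteinEncoding", c("Gene", "Protein"),
                      key = c("Gene", "Protein"))),
    tables = list(Gene = gene, Protein = protein, EquivalentGenes = equivalent,
                  GeneProteinEncoding = encoding))

  th <- type_hierarchy(list(
    c("identifier", "entity"),
    c("gene", "identifier"),
    c("gene name", "gene"),
    c("protein", "identifier"),
    c("name", "entity"),
    c("protein name", "name"),
    c("organism", "entity"),
    c("plant", "organism"),
    c("function", "entity"),
    c("molecular function", "function"),
    c("biological process", "function"),
    c("sequence", "entity"),
    c("relationship", "entity")))

  o <- ontology(
    concepts = tibble(
      name = c("gene", "protein", "organism", "function"),
      type = c("gene", "protein", "organism", "function")),
    associations = list(
      list(name = "partof", source = "gene", target = "organism"),
      list(name = "has", source = "gene", target = "function"),
      list(name = "encode", source = "gene", target = "protein"),
      list(name = "alias", source = "gene", target = "gene"),
      list(name = "function", source = "protein", target = "function")),
    rules = c(
      "function(X, Y) <- alias(X, Z), has(Z, Y)",
      "alias(X, Y) <- homolog(X, Y)",
      "alias(X, Y) <- ortholog(X, Y)",
      "alias(X, Y) <- gene(X), encode(X, Y)"),
    types = th)

  lex <- delta_lexicon()
  reg <- delta_registry(db, homology_threshold)
  structure(list(db = db, ontology = o, lexicon = lex, registry = reg),
            class = "coop_world")
}

delta_lexicon <- function() {
  g <- function(surface, lemma = surface, pos = NA, type = NA, canonical = NA) {
    tibble(surface = surface, lemma = lemma, pos = pos, type = type,
           canonical = canonical)
  }
  lexicon(bind_rows(
    # organisms (typing + query literals)
    g("human", pos = "noun", type = "organism", canonical = "Human"),
    g("humans", "human", "noun", "organism", "Human"),
    g("dog", pos = "noun", type = "organism", canonical = "Dog"),
    g("dogs", "dog", "noun", "organism", "Dog"),
    g("chimpanzee", pos = "noun", type = "organism", canonical = "Chimpanzee"),
    g("chimpanzees", "chimpanzee", "noun", "organism", "Chimpanzee"),
    g("plant", pos = "noun", type = "organism", canonical = "Plant"),
    # function vocabulary
    g("growth control", type = "function", canonical = "growth control"),
    g("electron transport", type = "function", canonical = "electron transport"),
    # relationship vocabulary (value concepts)
    g("ortholog", pos = "noun", type = "relationship", canonical = "Ortholog"),
    g("orthologs", "ortholog", "noun", "relationship", "Ortholog"),
    g("homolog", pos = "noun", type = "relationship", canonical = "Homolog"),
    g("homologs", "homolog", "noun", "relationship", "Homolog"),
    # protein names (typing only)
    g("ubiquinol-cytochrome c reductase complex chaperone", type = "protein name"),
    g("cytochrome b-c1 complex subunit 7", type = "protein name"),
    g("ubiquinol-cytochrome c reductase chaperone homolog", type = "protein name"),
    # grammar: nouns for schema vocabulary
    g("gene", pos = "noun"), g("genes", "gene", "noun"),
    g("protein", pos = "noun"), g("proteins", "protein", "noun"),
    g("organism", pos = "noun"), g("organisms", "organism", "noun"),
    g("function", pos = "noun"), g("functions", "function", "noun"),
    g("sequence", pos = "noun"), g("sequences", "sequence", "noun"),
    g("growth", pos = "noun"), g("control", pos = "noun"),
    # verbs
    g("list", pos = "verb"), g("print", pos = "verb"), g("return", pos = "verb"),
    g("show", pos = "verb"), g("find", pos = "verb"),
    g("encode", pos = "verb"), g("encodes", "encode", "verb"),
    g("encoded", "encode", "verb")))
}

delta_registry <- function(db, homology_threshold = 0.9) {
  gene_tb <- db$tables$Gene
  organism_tbl <- c(
    stats::setNames(as.list(gene_tb$Organism), gene_tb$GeneID),
    stats::setNames(as.list(gene_tb$Organism), gene_tb$GeneName))
  eq <- db$tables$EquivalentGenes
  id_tbl <- c(
    stats::setNames(as.list(eq$Relationship),
                    paste(eq$Object1, eq$Object2, sep = "\r")),
    stats::setNames(as.list(eq$Relationship),
                    paste(eq$Object2, eq$Object1, sep = "\r")))
  genemapper_tbl <- stats::setNames(as.list(gene_tb$GeneID), gene_tb$GeneName)
  seq_of <- c(stats::setNames(as.list(gene_tb$DNASequence), gene_tb$GeneID),
              stats::setNames(as.list(gene_tb$DNASequence), gene_tb$GeneName))
  homolog_fn <- function(args) {
    s1 <- seq_of[[args[1]]]; s2 <- seq_of[[args[2]]]
    if (is.null(s1) || is.null(s2)) return(NA_character_)
    if (sequence_identity(s1, s2) >= homology_threshold) "Homolog" else NA_character_
  }
  function_registry(
    registry_function("OrganismMapper", inputs = "gene", output = "organism",
                      fn = table_mock(organism_tbl)),
    registry_function("IDMapper", inputs = c("gene", "gene"),
                      output = "relationship", fn = table_mock(id_tbl)),
    registry_function("GeneMapper", inputs = "gene name", output = "gene",
                      fn = table_mock(genemapper_tbl)),
    registry_function("Homolog", inputs = c("gene", "gene"),
                      output = "relationship", fn = homolog_fn,
                      params = list(theta = homology_threshold)),
    registry_function("GeneCards", inputs = "gene name", output = "gene",
                      mode = "live"))
}

#' @export
print.coop_world <- function(x, ...) {
  cat("<coop_world>\n")
  print(x$db)
  print(x$ontology)
  invisible(x)
}

#' Generate a randomized schema/ontology/instance world
#'
#' Supports property testing: draws a random multi-relation schema with
#' declared keys, a compatible flat type tree and ontology, and an
#' instance in which values carry explicit `type::value` tags so column
#' typing is exact.  The construction guarantees at least one
#' entity-mapped concept (the first relation's single-attribute key) and
#' at least one value-mapped concept (a concept whose name is planted as
#' an instance value).  Identical seeds produce identical worlds.
#'
#' @param seed integer seed.
#' @param n_relations,n_concepts world size (both at least 1).
#' @return a `coop_world` list (`db`, `ontology`, `lexicon`, `registry`).
#' @export
random_world <- function(seed, n_relations = 3L, n_concepts = 3L) {
  if (n_relations < 1L || n_concepts < 1L) {
    stop_coop("random_world() needs n_relations >= 1 and n_concepts >= 1",
              "parameter_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed %% .Machine$integer.max)

  types <- c(paste0("t", seq_len(n_concepts + 2L)), "vt")
  th <- type_hierarchy(tibble(child = types, parent = "entity"))
  concept_names <- paste0("c", seq_len(n_concepts))
  concept_types <- types[seq_len(n_concepts)]

  schemas <- list(); tables <- list()
  for (r in seq_len(n_relations)) {
    rel <- paste0("R", r)
    n_attr <- sample(2:5, 1L)
    attrs <- paste0(rel, "A", seq_len(n_attr))
    # attribute types: key gets a concept type (relation 1 anchors concept 1)
    a_types <- sample(setdiff(types, "vt"), n_attr, replace = TRUE)
    a_types[1L] <- if (r == 1L) concept_types[1L] else sample(concept_types, 1L)
    schemas[[rel]] <- relation_schema(rel, attrs, key = attrs[1L])
    n_rows <- sample(5:12, 1L)
    cols <- map(seq_len(n_attr), function(j) {
      if (j == 1L) {
        paste0(a_types[1L], "::", rel, "k", seq_len(n_rows))
      } else {
        paste0(a_types[j], "::v", sample(1:30, n_rows, replace = TRUE))
      }
    })
    names(cols) <- attrs
    tables[[rel]] <- as_tibble(cols)
  }
  # plant a value concept: its name appears as a stored value, and no
  # column carries its type
  value_concept <- "plantedvalue"
  host <- tables[[1L]]
  if (ncol(host) >= 2L) {
    host[[2L]][1L] <- value_concept
    tables[[1L]] <- host
  }
  db <- database(schemas, tables)

  associations <- list()
  # one association per relation with >= 2 attributes: key concept to the
  # concept of another column when that column carries a concept type
  ctype_of <- stats::setNames(concept_names, concept_types)
  for (r in seq_len(n_relations)) {
    rel <- paste0("R", r)
    sc <- schemas[[rel]]
    if (length(sc$attributes) < 2L) next
    key_type <- sub("::.*$", "", tables[[rel]][[1L]][1L])
    other_type <- sub("::.*$", "", tables[[rel]][[2L]][nrow(tables[[rel]])])
    if (key_type %in% names(ctype_of) && other_type %in% names(ctype_of) &&
        key_type != other_type) {
      associations[[length(associations) + 1L]] <- list(
        name = paste0("rel", r), source = ctype_of[[key_type]],
        target = ctype_of[[other_type]])
    }
  }
  o <- ontology(
    concepts = tibble(name = c(concept_names, value_concept),
                      type = c(concept_types, "vt")),
    associations = associations,
    rules = character(),
    types = th)
  structure(list(db = db, ontology = o,
                 lexicon = lexicon(tibble(surface = character())),
                 registry = function_registry()),
            class = "coop_world")
}
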