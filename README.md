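# ontoscout

Ontology-guided search and exploration of annotated dataset repositories.

Biomedical data repositories describe their datasets with free-text
metadata and, increasingly, with terms from bio-ontologies (cell types,
organisms, diseases, assays, ...). Plain text search finds a dataset you can
already name; it fails when you want to learn what a repository *contains*,
or when the datasets you need are annotated with subtypes of the concept you
searched for. ontoscout is a library + CLI for the computational side of
that problem, aimed at repository maintainers, data curators and tool
builders: it turns one or more ontologies plus a tabular dataset manifest
into a pruned, statistics-bearing *exploration graph*, answers combined
free-text / Boolean annotation-term queries over it, and computes
visualization-ready treemap and layered node-link geometry for any renderer.

## The model

Ontologies are merged into one directed acyclic subclass graph `G = (V, E)`
with a single virtual root (`OWL:Thing`). Every term `t` has a *set
representation* `S_t`: the set of datasets annotated with `t` or any of its
descendants (the transitive annotation closure), and `|S_t|` is the term's
*size*. Because most of an ontology is never used for annotation, the graph
is pruned in two steps:

1. terms with `|S_t| = 0` are hidden;
2. a non-root term whose dataset set equals a child's is absorbed into that
   child (the deepest such term is kept), so that along every surviving
   edge the child's set is a **strict** subset of its parent's:
   `S_A ⊂ S_B ⊂ S_C` for a subclass chain `A ⊂ B ⊂ C`.

Absorbed ancestors are retained as per-term provenance so breadcrumb paths
can still show the full lineage.

For any retrieved result set `R`, each term carries two navigation signals:

    precision(t) = |R ∩ S_t| / |R|        recall(t) = |R ∩ S_t| / |S_t|

Precision says how characteristic a term is of what you just retrieved;
recall (the "information scent") says how much annotated material for that
term you have *not* yet retrieved. Queries combine conjunctive,
synonym-expanded text search (BM25-style ranking, title weighted 3x) with
Boolean term sets (`and` / `or` / `not`) and subtree rooting, evaluated as
pure set algebra over the `S_t`.

## Worked example

A classic worked scenario: a repository of 20 mouse immunology datasets in
which 12 are annotated with subtypes of *leukocyte* (T cell, B cell,
macrophage), but no free text ever says "leukocyte".

```r
library(ontoscout)

fx <- named_fixture("leukocyte_scenario")   # OBO + manifest, loaded via the parsers
built <- build_exploration_graph(fx$graph, fx$repo)
eg <- built$eg; idx <- built$index

text_search("leukocyte", fx$repo, fx$graph)
#> <result_set> 0 datasets

# browse instead: datasets under 'native cell' that are not precursor cells
r <- evaluate_term_query(term_query(and = "CL:0000003", not = "CL:0000011"), idx)
r
#> <result_set> 5 datasets
#>   DS08, DS09, DS10, DS11, DS12

recall("CL:0000738", r, idx)      # leukocyte
#> [1] 0.4166667
```

The recall of *leukocyte* is 5/12 < 0.5: less than half of the
leukocyte-related material was retrieved, so the term is worth a direct
query — which returns all 12 datasets:

```r
length(evaluate_term_query(term_query(and = "CL:0000738"), idx))
#> [1] 12
```

The same pipeline from the shell:

```sh
inst/scripts/ontoscout index --ontology CL=ontology.obo --manifest manifest.tsv --out idx/
inst/scripts/ontoscout query --index idx/ --query '"mouse" +term:CL:0000003 -term:CL:0000011'
inst/scripts/ontoscout layout --index idx/ --kind treemap --depth 2
```

## Package layout

- `R/ontology-graph.R`, `R/ontology-io.R` — subclass property graph, OBO /
  OWL RDF-XML parsing, GraphML / JSON export.
- `R/repository.R` — manifest parsing, transitive annotation index.
- `R/pruning.R` — strict-containment pruning, exploration graph.
- `R/metrics.R` — per-term precision / recall statistics.
- `R/query.R` — text + Boolean term query engine, KWIC snippets, data cart.
- `R/layout.R` — squarified treemap and layered node-link geometry.
- `R/fixtures.R` — deterministic synthetic-fixture generator and named
  scenario fixtures.
- `R/cli.R` — `cmd_*` functions and the `inst/scripts/ontoscout` entry
  point.

See `vignettes/exploration-graphs.Rmd` for the methods description.
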