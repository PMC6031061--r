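---
title: "Building strict-containment exploration graphs from annotated repositories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building strict-containment exploration graphs from annotated repositories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoscout)
```

## The problem

A dataset repository annotated with ontology terms is, structurally, a
polyhierarchy of attributes laid over a collection of atomic datasets. Each
dataset carries *direct* annotation terms; through the transitive subclass
relation, every superclass of a direct term is an *indirect* annotation of
the same dataset. The quantity everything in this package revolves around is
the set representation of a term $t$,

$$S_t = \{\, d : d \text{ annotated with } t \text{ or any descendant of } t \,\},$$

with $|S_t|$ the term's **size**. ontoscout computes these sets, reduces the
ontology graph to the part that carries information about the repository,
and derives per-term search statistics and layout geometry from them.

## From ontologies to the exploration graph

`load_ontology()` reads OBO 1.4 or OWL RDF/XML into a simplified property
graph: one node per named class, one edge per asserted named-class
subsumption, everything parentless attached to a single virtual root
(`OWL:Thing`). Anonymous classes, restriction expressions and equivalence
axioms are deliberately not materialized — the exploration model needs the
subsumption skeleton, not a reasoner; the OWL reader is structured so other
relation types could be added, but none are by default. Multiple ontologies
merge into one graph; a class imported by several ontologies becomes a
single node whose `ontology_tags` records every source, so the merged graph
can be traversed as one structure while class origin stays traceable.

Cycles are a hard error rather than silently broken: all downstream
computation (closure, pruning, distances, layouts) assumes a DAG, and an
accidental subsumption cycle is a curation bug worth surfacing, with the
offending classes listed.

Identifiers are normalized to CURIE form through a configurable prefix map;
IRIs with unknown prefixes are kept verbatim so identity is never lost.
Normalization is idempotent.

Pruning happens in two passes on top of the annotation closure:

1. **Hiding unused terms** (`restrict_to_used()`): only terms with
   $|S_t| \ge 1$ survive, plus the root. In real collections this is a
   drastic cut — typically a few hundred used terms out of millions across
   the source ontologies.
2. **Collapsing redundant ancestors** (`collapse_redundant_parents()`): a
   non-root term with a child of identical set describes exactly the same
   datasets as that child, so it is absorbed into the child, to a fixpoint.
   The surviving hierarchy satisfies strict containment along every edge:
   for each retained edge $(c, p)$ with non-root $p$, $S_c \subsetneq S_p$.
   If all datasets are, say, human, every ancestor of *human* up to the root
   collapses onto *human*.

Two design points here were genuinely open:

* **Which term of an equal-set chain to keep.** We keep the deepest (most
  specific) term — the one closest to the actual annotations — and record
  the absorbed ancestors in the term's `provenance`, which breadcrumb paths
  interleave as display-only entries. Candidates are processed in
  decreasing root distance, which makes the result deterministic and
  independent of storage order.
* **Equal-set parents with several children.** A parent whose set equals
  the *union* of two or more strictly smaller children is kept: every edge
  below it is already strict, and removing it would disconnect siblings.
  But a parent with several children where one child's set equals the
  parent's own cannot keep that edge (it would violate strict containment);
  such a parent is absorbed into the equal child and its remaining children
  re-link to the grandparents. They stay connected, every surviving edge is
  strict, and no parent-child relation is invented between former siblings.
  A related boundary case: an ancestor whose set covers the whole
  repository is retained only while it has two or more retained children;
  with a single equal-set child it collapses like any other term.

Pruning never alters $S_t$ for a retained term — sets are computed on the
full graph before pruning and preserved — and every annotated dataset
remains reachable at the root.

## Precision and recall as navigation signals

Given a retrieved result set $R$ (from any query), each retained term gets

$$\mathrm{precision}(t) = \frac{|R \cap S_t|}{|R|}, \qquad
  \mathrm{recall}(t) = \frac{|R \cap S_t|}{|S_t|}.$$

Precision describes the current retrieval (how characteristic is this term
of what I found); recall is an information-scent signal (how much material
annotated with this term exists that I did *not* retrieve). Both divide the
same integer intersection count, so
$\mathrm{precision}\cdot|R| = \mathrm{recall}\cdot|S_t|$ holds exactly.
Undefined values — empty result set, unused term — raise classed errors or
are flagged `NA` in the statistics table, never silently reported as 0,
because 0 is a meaningful value in displays. When the result set is the
whole repository, recall is 1 everywhere and precision equals
$|S_t|/|U|$; this is why the node-link view sorts by precision by default.

```{r}
fx <- named_fixture("leukocyte_scenario")
built <- build_exploration_graph(fx$graph, fx$repo)
r <- evaluate_term_query(term_query(and = "CL:0000003", not = "CL:0000011"),
                         built$index)
recall("CL:0000738", r, built$index)   # 5 of 12 leukocyte datasets retrieved
```

## Query semantics

A query combines a text part and a term part.

* **Text search** is case-insensitive, tokenized on non-alphanumerics with
  no stemming, and *conjunctive*: every query token must match in the
  title, description or attribute text. With synonym expansion on, a token
  that matches an ontology term's label also matches that term's synonyms
  ("mouse" finds descriptions saying only "mice"). Ranking is a BM25-style
  score with field weights (title 3, description 1, attribute text 1),
  without document-length normalization — metadata records are short and
  uniform — and deterministic id tie-breaks. Matching annotation *labels*
  from free text is off by default (config flag `match_labels`): keeping
  the two retrieval routes distinct is precisely what makes the per-term
  recall signal interpretable.
* **Term queries** are pure set algebra over the $S_t$: the AND terms are
  intersected first, the OR union is intersected with that (or with the
  universe when no AND terms exist), the NOT union is subtracted last as an
  absolute exclusion, and the optional root term's set is intersected
  finally. Rooting a view at a term and then querying is identical to
  adding the root term to the query — the two operations commute.
* A term cycles through the four query states
  `none → or → and → not → none`.

The combined result is the intersection of both parts, ordered by the text
ranking. A canonical string syntax (`free text +term:ID ~term:ID -term:ID
root:ID`) round-trips through `parse_query()` / `format_query()` and drives
the CLI.

## Layout geometry

Both layouts are computed as data in the unit square (origin top-left,
half-open rectangles); no pixels are rendered.

* **Treemap**: squarified tiling, chosen because it is the standard for
  legible aspect ratios; siblings enter in size-descending order (ties by
  label, then id) and rows are closed when adding another sibling would
  worsen the row's worst aspect ratio. Sibling areas are proportional to
  term sizes *within the sibling group* — in a polyhierarchy sibling sets
  may overlap, so areas are normalized by the sibling-size sum and are
  deliberately not comparable to the root. A term with several retained
  parents is tiled under each of them, following treemap convention. The
  color channel is emitted as an integer level equal to the term's subtree
  depth (distance to its farthest descendant), leaving palette choice to
  the renderer. Child areas tile the parent exactly (tested to 1e-9).
* **Node-link**: terms are placed in columns indexed by their distance to
  the root *in the pruned graph* (self-consistent with the edges actually
  displayed; original-ontology distance would disagree with them whenever
  provenance chains were absorbed). Columns sort by precision descending by
  default, with recall, size and name as alternatives, ties by label then
  id. For a visible window (first column, column count, rows per column),
  each visible term counts its incoming and outgoing edges whose partner is
  hidden, which the interface renders as hidden-link bars.

## Synthetic fixtures

The generator (`generate_fixture()`) emulates the regime the method is
designed for: a multi-level subclass DAG (rank assignment plus
parent-sampling from lower ranks, acyclic by construction; a configurable
fraction of terms get a second parent) in which only a small fraction of
terms is ever used for annotation, and datasets annotated at varying
depths. Defaults (60 terms, depth 6, 15% polyhierarchy, 40 datasets, 30%
of terms used, 1–4 annotations per dataset) mirror a small curated
collection — on the order of a hundred datasets annotated against a handful
of ontologies. Generation is deterministic per seed and leaves the global
RNG stream untouched; fixtures are emitted as OBO + TSV text and reloaded
through the package's own parsers, so fixture tests always exercise the
loader path.

Four named fixtures encode canonical scenarios: an all-human chain under
Mammalia (ancestor collapse), a leukocyte browsing scenario (12 datasets
annotated with leukocyte subtypes, 5 of them retrievable as native-but-not-
precursor cells, none mentioning "leukocyte" in free text), a four-dataset
repository realizing the four precision/recall cases, and a three-species
taxonomy with collapsible inner chains. One fixture-design note: in a
four-dataset repository, a search that retrieves everything necessarily has
recall 1 for every term, so the low-precision/low-recall case is realized
with a narrow search (where an unrelated term scores 0 on both), while the
0.25-precision broad-search case is asserted separately.

What passing on these fixtures does **not** show: real ontologies bring
scale (millions of classes), messier structure (equivalence axioms,
cross-ontology imports, near-cycles through curation errors) and noisier
annotation practice than the generator produces. The loaders and the
pruning laws are exercised; curation quality is not simulated.

## Numerical and degenerate-input choices

* Treemap tiling tolerance 1e-9; all set computations are exact integer /
  string operations.
* All orderings carry explicit deterministic tie-breaks (label, then id),
  so repeated runs are byte-identical.
* Empty repository: the exploration graph is just the root; the CLI warns
  and still emits valid (minimal) documents. Empty result sets make
  precision/recall errors by design.
* Annotation terms missing from the ontologies never abort an index build;
  they are collected into an unresolved-terms report (TSV) for curators.
* Problem sizes in the test-suite: property sweeps use 200 generated
  fixtures of up to 60 terms and 40 datasets against brute-force oracles;
  the scalability check builds a fixture with over 1000 retained
  annotation terms (4000-term ontology, 500 datasets) through the full
  pipeline including both layouts.

## Known limitations

* No OWL reasoning: only asserted subsumptions are used; inferred
  subsumption or equivalence merging would change $S_t$ for repositories
  annotated against rich OWL ontologies.
* Annotations attach at dataset level; file-level annotation within a
  dataset is out of scope, as is full ISA-Tab parsing.
* Ontology versioning — tracing how the exploration graph changes as
  ontologies or curation evolve — is unaddressed.
* Choosing *which* class of a collapsed equal-set branch to keep is done by
  depth; smarter, semantics-aware selection is an open opportunity.
* The interactive browser (rendering, transitions, highlighting mechanics)
  is explicitly out of scope; this package produces the sets, statistics
  and geometry a renderer would consume.
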