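---
title: "Integrating parallel disease classifications with statement-level provenance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating parallel disease classifications with statement-level provenance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skosmerge)
```

## The model

`skosmerge` represents a disease classification as a knowledge graph with
five entity kinds — disorder groups, disorders, genes, phenotypes and modes
of inheritance — and six statement predicates. Two design commitments drive
everything else.

**Grouping and sub-typing are different relations.** Classical taxonomies
overload the sub-class relation: "Acrodysostosis is a sub-class of Acromelic
dysplasias" really means *membership* in a group, while "Mesomelic
dysplasia, Korean type is a sub-class of Mesomelic dysplasia" means
*specialisation*. Here groups are SKOS Collections and membership is
`MEMBER` (`skos:member`), which permits multi-group placement and
arbitrarily nested groups; sub-typing is the transitive pair
`BROADER_T`/`NARROWER_T`. `BROADER_T(a, b)` states that disorder `a` is
conceptually broader than disorder `b`; the model materialises the inverse
`NARROWER_T(b, a)` with identical attribution on every insertion, and both
directed relations are kept acyclic (a cycle under transitivity would make
every member broader than itself, so insertions closing a cycle are
rejected rather than tolerated). `broader_closure()` returns the full
transitive relation.

One wording caution: in the W3C SKOS vocabulary the property
`skos:narrowerTransitive` points *from* the broader concept *to* its
narrower sub-type ("has narrower"), and `skos:broaderTransitive` the other
way around. The serializer therefore maps the statement
`BROADER_T(a, b)` — "a is broader than b" — onto the triple
`a skos:narrowerTransitive b`, and its materialised inverse onto
`b skos:broaderTransitive a`. Both vocabulary properties appear in the
output, subject-preserving and with the standard SKOS reading.

**Provenance is recorded on every statement, not only on entities.** Every
entity and every statement carries a non-empty set of agent identifiers
(`prov:wasAttributedTo`). Statement identity is the tuple
*(subject, predicate, object, qualifier)*: re-asserting an identical
statement unions attribution sets (attribution is monotone — no operation
ever removes an agent), while the same disorder–phenotype pair under two
different frequency qualifiers remains two statements. This is deliberate:
each source's assertion is preserved verbatim, and conflicting assertions
coexist side by side with their provenance rather than being reconciled.
Consumers who need a consistent single-perspective graph take a
`provenance_view()` instead.

The frequency qualifier vocabulary (`OBLIGATE`, `VERY_FREQUENT`,
`FREQUENT`, `OCCASIONAL`, `VERY_RARE`, `UNSPECIFIED`) is this package's
closed enumeration of the Orphanet-style degree-of-occurrence annotations;
an absent qualifier is normalised to `UNSPECIFIED`, and qualifiers are only
admitted on phenotype associations.

## Merging under an expert alignment

Cross-source identity is an expert judgement, not a computation: the merge
consumes a manually curated alignment table and performs no lexical or
structural matching. Aligned clusters (closed transitively across source
pairs by union-find, so three or more sources compose) receive one
canonical identifier; minting is deterministic — aligned clusters first,
then unaligned entities, each ordered by (agent id, local id), numbered
`BD…`/`BDG…`/`GENE…` with seven-digit padding — which makes the merge
independent of the order in which sources are supplied. Phenotypes and
modes of inheritance are HP CURIEs shared by construction and pass through
unchanged. The numbering scheme itself is a package convention; nothing
downstream depends on particular numerals.

When the aligned records disagree on whether a node is a group or a
disorder, precedence is: explicit expert decision in the alignment row,
then agreement of the declared kinds, then the advisory heuristic
`classify_node_kind()`: a node whose children are all disorders linked only
by sub-typing — each with the node as its sole broader parent per asserting
agent — behaves as a disorder with sub-types (the Mesomelic dysplasia
pattern); a node with any group child, or mixing groups and disorders,
behaves as a group (the Dysostosis pattern, whose members include two
groups and the disorder Congenital pseudoarthrosis of clavicle). The
heuristic is advisory only and never mutates declared kinds. A childless
node keeps its declared kind; a node whose sub-typed children have
additional broader parents also falls back to the declared kind rather than
being forced to either verdict.

Labels: the preferred label of the lexicographically first asserting agent
wins and all other labels become `skos:altLabel`s — a deterministic
tie-break, not a quality judgement. Cross-reference values are unioned per
namespace; clashing values within one namespace are both kept and flagged
in the merge report.

Two properties characterise the merge and are enforced by the test suite as
oracle-checked invariants: it is *lossless* (every source statement appears
in the merged graph under the canonical map, with its agent in the
attribution) and *conservative* (no statement carries an agent whose source
did not assert it). Together they yield the backwards-compatibility
guarantee: `provenance_view(merge(A, B), agents(A))` is isomorphic to the
ingested `A`.

## Serialization

The Turtle dialect emits, per entity, its punned typing (disorders and
genes are simultaneously `owl:Class` and `skos:Concept` instances; groups
are `skos:Collection`s), labels, per-namespace cross-references and
attribution triples; per statement, one plain triple in the SKOS/RBDO
vocabulary plus one `owl:Axiom` node with the three annotated-triple links
and one attribution triple per agent. Frequency qualifiers annotate the
axiom node, keeping the plain triple identical to the unqualified case.
OWL restriction semantics for the association relations are represented at
the data level only; no class expressions are emitted, and no
description-logic reasoning is attempted.

Output is canonical: prefixes, header, agents, entities, statements, each
block sorted lexicographically, one triple per line, blank axiom nodes
numbered in statement order. Equal graphs therefore serialize to
byte-identical text, and `read_turtle()` inverts `write_turtle()` exactly.
The reader is a dialect reader: it rejects triples outside the dialect and
axiom nodes missing any of their three links, naming the offending subject.
It does not attempt to ingest arbitrary third-party RDF.

## The synthetic fixture generator

`generate_fixture()` emulates the two-source situation the package is
built for: a nosology-style source and a deeper Orphanet-style source with
partially overlapping disorder sets. Defaults (per source: 24/20 disorders,
6/5 groups, alignment covering 60% of the smaller disorder set, a shared
vocabulary of 60 synthetic phenotype codes, 2–6 phenotype associations per
disorder with 35% common assertions per aligned pair, nesting up to 4
levels, Orphanet-side frequency qualifiers) are scaled-down echoes of the
real resources, where roughly 61% of the nosology's disorders have
counterparts, phenotype annotation sets overlap only partially (on the
order of a third of the smaller set for well-described disorders), and the
two taxonomies nest 3 versus up to 7 levels. The sizes are chosen so that
property suites over tens of fixtures run in seconds; the structure, not
the scale, is what the properties exercise.

What the generator does *not* emulate: lexical variation in labels (expert
alignment is taken as given, so label noise would exercise nothing),
HPO's internal hierarchy (phenotype matching is exact-identifier only),
annotation errors, and real-world size. Passing tests therefore demonstrate
the algebraic correctness of merge/view/serialization on realistic
*structure*, not robustness to noisy real-world inputs.

Generation is driven by a single seed through R's RNG with the caller's
RNG state restored afterwards; identical parameters and seed give
byte-identical bundles. The manifest (aligned counts, per-disorder overlap
triples, per-source depth) is written at generation time by direct counting
with a plain recursive path enumeration, independent of the analytics
module it later validates.

The worked-examples bundle (`worked_examples_fixture()`) is hand-written,
uses the domain's real disorder/gene/phenotype names for traceability, and
encodes the canonical illustrative cases: split group membership with
per-source attribution, a gene association asserted by both sources, an
OMIM-attributed phenotype, the Holt-Oram member-vs-subtype divergence, the
three-disorder Polydactyly chain, the Rubinstein-Taybi narrower pair, the
mixed Dysostosis group and the Mesomelic dysplasia sub-typing family.

## Analytics conventions

* *Common association sets*: "common to all sources" means the intersection
  over the agents that annotate the disorder in that category (phenotypes
  and genes intersect separately). Interpreting it over *all* graph agents
  would empty the common set for any disorder absent from one source,
  defeating the query's purpose.
* *Coverage* is entity-level: a disorder counts for an agent iff the agent
  attributes the entity, regardless of how many statements mention it.
  Percentages are rounded half-up to one decimal (202 of 524 prints as
  38.5). Per-disorder overlap triples count distinct phenotype identifiers
  exactly; HPO-ancestor-aware matching would be a possible extension but is
  deliberately out of scope.
* *Divergence* compares, per disorder attributed to at least two agents,
  the per-agent parent sets (group memberships and broader parents, tagged
  by relation); any inequality flags the disorder.
* *Depth* counts edges, not nodes, along the longest downward path over
  membership and sub-typing edges combined, since real taxonomies mix both
  within one hierarchy. The combined relation is acyclic by construction
  (membership cycles and sub-typing cycles are rejected at insertion, and
  no edge can lead from a disorder back to a group).

## Numerical and degenerate-input choices

Graphs with no entities, no statements, or no hierarchy edges are valid:
closures are empty relations, depth is 0, fact-sheet counts are 0, and an
empty graph serializes to the prefix/header block alone. Validation is
report-based (`kg_validate()` lists every violation rather than stopping at
the first), while the mutating operations fail fast with typed conditions
(`KindClash`, `DanglingEndpoint`, `CycleIntroduced`, `EmptyAttribution`,
...). Agent identifiers are case-sensitive tokens in an open registry —
sources beyond the original three can be added without touching the model,
which is what makes incorporating an additional classification a data
exercise rather than a code change.

## Known limitations

* The alignment must be functional per source pair; modelling genuine
  one-to-many expert mappings would require a different table semantics.
* A disorder may simultaneously be sub-typed under one source and
  group-assigned under another (Holt-Oram); the model retains both edges
  and deliberately offers no precedence rule between them.
* The Turtle reader handles only this package's dialect.
* Phenotype identity is exact-id; no use is made of the HP hierarchy.
* The advisory kind heuristic inspects asserted children only; it cannot
  classify a node whose evidence lives entirely in another source's view of
  an unaligned sibling.
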