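# skosmerge

Integrates multiple expert classifications of a disease domain into a single
knowledge graph with statement-level provenance, and provides the analytics
that make the integrated resource useful: per-source views, coverage
statistics, association comparison and divergence reports.

## The problem

Rare-disease domains are often classified in parallel by several expert
communities. In the rare bone disorder (skeletal dysplasia) domain, a
nosology revised by a society of experts places each disorder in exactly one
group, while a second taxonomy nests disorders up to seven levels deep,
mixes *grouping* ("Achondroplasia is a member of the FGFR3 chondrodysplasia
group") with *sub-typing* ("Mesomelic dysplasia, Korean type is a type of
Mesomelic dysplasia"), and attaches frequency-qualified phenotype
annotations. The two sources disagree: hundreds of disorders appear in only
one of them, their phenotype vocabularies differ, and the same disorder can
be a group member in one source and a sub-type in the other (Holt-Oram
syndrome). Neither source is "right" — the disagreements are genuine
differences of expert opinion, so an integration must retain both views and
say who asserted what.

`skosmerge` implements that loose integration:

* **Grouping vs sub-typing** get distinct semantics: groups are SKOS
  Collections linked to members via `skos:member` (groups may nest, and a
  disorder may sit in several groups); sub-typing uses the mutually inverse
  transitive relations (`skos:broaderTransitive` / `skos:narrowerTransitive`),
  so a chain Polydactyly → Preaxial polydactyly of fingers → Polydactyly of
  a triphalangeal thumb entails the endpoint pair in the transitive closure.
* **Provenance at every granularity**: each entity *and each statement*
  carries a non-empty `prov:wasAttributedTo` agent set (ISDS, OMIM,
  Orphanet, ...). Identical statements from several sources merge into one
  statement with a unioned attribution set; conflicting statements coexist,
  each with its own provenance.
* **Expert alignment as data**: cross-source equivalences come from a
  manually curated alignment table (TSV), including the expert's
  group-vs-disorder decision; an advisory heuristic (children all sub-types
  ⇒ disorder; a mixture of groups and disorders ⇒ group) breaks ties when
  the decision is `AUTO`.
* **OWL 2-style serialization**: a deterministic Turtle dialect with punning
  (a disorder is both a class and a SKOS Concept instance) and one annotated
  axiom (`owl:annotatedSource/Property/Target` + attribution) per statement.
  `read_turtle(write_turtle(g))` is the identity, and equal graphs serialize
  byte-identically.
* **Backwards compatibility as an operation**: `provenance_view(g, agents)`
  recreates any contributing classification from the merged graph.

## Worked example

The package ships a reconstruction of the domain's canonical worked
examples as a two-source fixture (`worked_examples_fixture()`):

```r
library(skosmerge)
fx  <- worked_examples_fixture()          # ISDS/BDO side + Orphanet side + alignment
res <- kg_merge(fx$sources, fx$alignment)
res$graph
#> <kg 'merged': 31 entities, 32 statements, agents: ISDS, OMIM, Orphanet>
#>    GROUP=9 DISORDER=15 GENE=2 PHENOTYPE=4 INHERITANCE_MODE=1

# Spondyloepimetaphyseal dysplasia Maroteaux type after the merge:
mid <- canonical_id(res$map, "ISDS", "sed_maroteaux")
association_comparison(res$graph, mid)
#> Association comparison for BD0000003
#>   phenotypes: common {HP:0002857}
#>     OMIM: 1 (1 unique)
#>   genes: common {GENE0000002}
#>     ISDS: 1 (0 unique)
#>     Orphanet: 1 (0 unique)
```

The disorder is a member of two groups — the Spondylo-epi(-meta)physeal
dysplasias (attributed to Orphanet) and the TRPV4 group (attributed to
ISDS); its TRPV4 gene association carries both agents, while its Genu
valgum phenotype is attributed to OMIM alone. Divergent placements are
flagged per disorder:

```r
grouping_divergence(res$graph)[, c("disorder", "divergent")]
#>    disorder divergent
#> 1 BD0000001      TRUE     # Achondroplasia: grouped on one side only
#> 2 BD0000002      TRUE     # Holt-Oram: group member vs sub-type of Heart-hand
#> 3 BD0000003      TRUE     # Maroteaux type: two different groups
```

And the original ISDS/BDO classification is recovered as a view:

```r
fact_sheet(provenance_view(res$graph, c("ISDS", "OMIM")))
#> Fact sheet
#>   Namespace              http://purl.org/skeletome/rbdo#
#>   Provenance agents      ISDS, OMIM
#>   ...
#>   disorders              4
#>   disorder groups        5
```

A command-line interface wraps the same operations
(`inst/scripts/skosmerge`):

```sh
skosmerge merge a.json b.json --alignment aln.tsv -o merged.ttl --report rep.json
skosmerge view merged.ttl --agents ISDS,OMIM -o view.ttl
skosmerge query merged.ttl --target GENE0000001 --format json
skosmerge coverage merged.ttl --left ISDS --right Orphanet
skosmerge fixture --out fixtures/ --seed 7
```

## Layout

* `R/model.R` — graph model: entities, statements, attribution, validation,
  transitive closure, the group-vs-disorder heuristic.
* `R/source_io.R` — JSON source documents, TSV alignment tables, the Turtle
  dialect, fact sheets.
* `R/merge.R` — canonical id minting (`BD`/`BDG`/`GENE` + HP pass-through),
  kind resolution, the merge and its report.
* `R/analytics.R` — provenance views, association comparison, coverage,
  divergence, depth, endpoint-style queries.
* `R/fixtures.R` — the synthetic two-source generator and the
  worked-examples bundle.
* `R/cli.R`, `inst/scripts/skosmerge` — the command-line adapter.
* `vignettes/integrating-classifications.Rmd` — the methods vignette.
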