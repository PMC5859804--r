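# fcamapr

Ontology matching for biomedical ontologies with Formal Concept Analysis
(FCA).

Large biomedical ontologies — anatomy, disease and clinical-term systems —
cover overlapping domains with different names, granularities and axioms.
`fcamapr` identifies correspondences between the classes (and object
properties) of two OWL ontologies by building a sequence of *formal
contexts* and reading mappings off the concept lattices they induce, rather
than by scoring string similarity. The method is score-free: a pair is
proposed when some commonality (shared tokens, shared structural relations,
shared restriction fillers) is *unique* to that pair.

## The formalism

A formal context is a triple K = (G, M, I) of objects, attributes and an
incidence relation. The derivation operators

    A' = { m ∈ M : g I m for all g ∈ A },   B' = { g ∈ G : g I m for all m ∈ B }

induce formal concepts (A, B) with A = B' and B = A', ordered by
(A₁,B₁) ≤ (A₂,B₂) ⇔ A₁ ⊆ A₂. Each concept carries a *simplified extent*
K_ex (the objects introduced at that concept, i.e. those g with γg = (A,B))
and dually a *simplified intent* K_in. Instead of the full (potentially
exponential) lattice, the package computes the polynomial-sized Galois
sub-hierarchy (AOC poset): exactly the object concepts γg and attribute
concepts μm with the induced order, which preserves all simplified labels.

Matching proceeds in five steps, each a new context:

1. **Token-based context** — objects: the class names, labels and synonyms
   of both ontologies; attributes: their canonical tokens. Concepts whose
   simplified extent holds exactly two strings, one per ontology, yield
   **Type I** (exact) anchors; concepts whose *class-origin extent* holds
   exactly two classes across ontologies yield **Type II** (unique partial)
   anchors.
2. **Relation-based context** — objects: all classes; attributes: anchors
   prefixed with `(ISA)`, `(SIB)`, `(PAT)` or the mixed conflict labels
   `(I-D)`/`(D-I)` (taxonomy on one side, disjointness on the other).
   Anchors co-occurring under positive labels support each other (sets
   P(a)); co-occurrence under mixed labels is negative evidence (N(a)).
   Conflicts are repaired greedily until every N(a) is empty, and Type II
   anchors without positive support are screened out.
3. **Positive relation-based context** — five positive labels (`ISA`,
   `SUPERCLASS-OF`, `SIBLING-WITH`, `PART-OF`, `HAS-PART`). Simplified
   extents with exactly one class per ontology give new one-to-one
   structural mappings; larger cross-ontology simplified extents give
   one-to-group and group-to-group complex candidates (disjunctions).
4. **Property-based context** — objects: object properties; attributes:
   ordered pairs of class mappings realized by an axiom `C ⊑ ∃g.D` /
   `C ⊑ ∀g.D` (asserted or inferred). Extents of exactly two
   cross-ontology properties yield property mappings.
5. **Restriction-based context** — fillers of the *anonymous ancestors*
   (inherited and filler-generalized quantified restrictions) of each
   anchor's two classes are paired under mapped properties; the resulting
   bipartite context yields extended one-to-one matches (singleton
   K_ex and K_in) and restriction-based complex candidates (empty K_in
   with non-empty K_ex, or the dual).

Alignments are written as OAEI Alignment RDF and scored with the standard
precision / recall / F-measure, with an optional "Unknown" category that is
excluded from both denominators.

## Worked example

```r
library(fcamapr)

fx <- make_fixture("ma_nci_combined")          # anatomy fragment pair
al <- run_pipeline(fx$onto1, fx$onto2, steps = 1:2, lexicon = fx$lexicon)
#> step 1: token context |G|=28 |M|=21 |I|=60, GSH 24 nodes, 13 anchors
#> step 2: 13 anchors repaired to 12, screened to 12
evaluate(al, fx$ground_truth)
#> correct 12 | incorrect 0 | unknown 0 | total 12 | reference 12
#> precision 1.000  recall 1.000  F-measure 1.000
```

Step 1 finds 13 lexical anchors, including the exact match between
`MA:mammary gland fluid/secretion` and the synonym "Mammary Gland Fluids
and Secretions" of `NCI:Breast Fluid or Secretion`, and unique-partial
matches such as `MA:adrenal gland zona fasciculata` ↔ `NCI:Fasciculata
Zone` (the token *fasciculata* occurs in exactly these two classes). Step 2
eliminates the conflicted `organ system` anchor — in the mouse-anatomy side
adipose tissue *is an* organ system while the cancer-thesaurus side asserts
the two disjoint — leaving an alignment that matches the fixture's ground
truth exactly.

Running all five steps on the cardiovascular/liver fixture surfaces
extended matches that share no tokens, e.g. `SNOMED:Structure of visceral
pericardium` ↔ `NCI:Epicardium`, plus a complex candidate pairing
`SNOMED:Vascular structure of liver` with a combination of `NCI:Blood
Vessel` and `NCI:Liver`:

```r
fx <- make_fixture("fig6_restriction")
al <- run_pipeline(fx$onto1, fx$onto2, steps = 1:5, quiet = TRUE)
subset(al$mappings, step == "5", c(class1, class2))
```

A command-line front end is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "fca-map.R", package = "fcamapr"))')
Rscript $CLI fixture ma_nci_combined --outdir demo
Rscript $CLI match demo/ma_nci_combined_1.owl demo/ma_nci_combined_2.owl \
        --steps 1,2 --out demo/sys.rdf
Rscript $CLI eval demo/sys.rdf demo/ma_nci_combined_reference.rdf
```

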