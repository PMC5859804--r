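---
title: "Matching ontologies through formal concept lattices: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching ontologies through formal concept lattices: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcamapr)
```

`fcamapr` aligns two OWL ontologies by clustering commonalities among their
classes and properties in a sequence of formal contexts and extracting
correspondences from the derived Galois sub-hierarchies. This vignette
documents the model, the tunable parameters, the synthetic-data generator,
and the numerical and design choices a maintainer should know about.

## The model and its assumptions

Formal Concept Analysis turns a binary object–attribute table into a
complete lattice of concepts `(extent, intent)`. The method exploits one
feature of that lattice above all: the *simplified labels*. An object `g`
labels the unique smallest concept containing it (its object concept `γg`),
an attribute `m` the unique largest concept whose intent contains it
(`μm`). A concept whose simplified extent contains exactly two entries is
therefore the witness that those two entries — and no others — share
exactly that combination of attributes. All extraction rules in the five
matching steps are instances of this "unique co-occurrence" reading:

* two strings with identical canonical token sets (Type I lexical anchor);
* two classes that are the sole owners of a token combination (Type II);
* two classes standing in the same taxonomic/partonomic relations to the
  validated anchors (structural one-to-one, or one-to-group /
  group-to-group when the simplified extent is larger);
* two object properties connecting exactly the same mapped class pairs;
* two restriction fillers that always occur together in the anonymous
  ancestors of anchors.

The assumptions this rests on: class names and annotations carry meaningful
domain vocabulary; taxonomies are reasonably deep so that structural
co-occurrence is discriminating; and disjointness axioms, where present,
are trustworthy enough to veto lexical matches. Ontologies violating these
(small, lexically idiosyncratic, or axiom-poor) will yield sparse contexts
and few or noisy mappings — the method degrades by emitting less, not by
emitting garbage with high confidence, because it has no scores to inflate.

Because the full lattice can be exponential in the context size, all
extraction works on the Galois sub-hierarchy (AOC poset): only `γg` and
`μm`, of which there are at most `|G| + |M|`. Every rule above only ever
inspects simplified labels (or full extents of such nodes), which the GSH
preserves exactly; `enumerate_concepts()` keeps the brute-force full
lattice as an in-package oracle, guarded to 20×20, and the test suite
checks GSH-vs-oracle equivalence on hundreds of random contexts.

## Inference regime

Both asserted and inferred relations feed the contexts, but no description
logic reasoner is involved. The closures are:

* strict transitive closure of ISA (a class is not its own ancestor);
* partonomy closure combining PART-OF edges with the taxonomy (parts are
  inherited by subclasses of the part; wholes generalize along their
  ancestors; PART-OF is transitive);
* inherited disjointness: `d` is disjoint-related to `c` when any
  ancestor-or-self of `c` is asserted disjoint with any ancestor-or-self of
  `d`;
* *anonymous ancestors*: a class holds every quantified restriction of its
  ISA ancestors (R1), and holding `Q r.C` implies `Q r.D` for every
  ancestor `D` of the filler `C` (R2), applied to both quantifiers.

R1/R2 reproduce the worked restriction examples exactly and keep the
package self-contained; they are deliberately weaker than a full EL
reasoner (no role chains, no conjunction reasoning). Siblinghood uses
direct parents only — closure-based siblinghood degenerates to
near-universal marks and would drown the relation context.

## Tunable parameters

| Parameter | Where | Default | Why |
|---|---|---|---|
| stop words | `token_lexicon()` | `a an and or of the in on to with nos` | the smallest list that collapses "Fluids and Secretions" with "fluid/secretion" and ignores the clinical suffix "NOS"; configurable per corpus |
| token variant map | `token_lexicon()` | empty | token-level synonymy/variation (e.g. `dorsum → back`); totalized so canonical tokens map to themselves; multi-word synonyms belong on the class as extra lexicalizations instead |
| plural stripping | `normalize()` | rule-based (`-ies → -y`, `-es`, `-s`) | reproduces the printed normalizations without an external lemmatizer; `-ss/-us/-is` endings are left alone |
| label / synonym annotation IRIs | `load_config()` | `rdfs:label`; oboInOwl related/exact synonyms | the annotations OAEI-style OWL exports actually use |
| PART-OF properties | `load_config()` | local names matching `part_of` | partonomy is a first-class relation, distinct from other object properties |
| ISA cycle policy | `load_config()` | fatal | real exports occasionally encode equivalence as 2-cycles; `"collapse"` merges each strongly connected component into its first member |
| steps | `run_pipeline()` | `1:5` | later steps consume earlier outputs, so the selection must be a contiguous prefix |

Class lexicalizations are the union of labels and synonym annotations; the
IRI local name is used only as a fallback when a class has neither. This
matches ontologies with opaque IRIs where the label *is* the name, and lets
a class contribute a synonym string without also contributing a
machine-generated name.

## Evidence, repair, and screening

Evidence follows the anchor-in-extent formulation: when a concept's extent
contains both classes of anchor `a`, then `a` is positive evidence for
every `(ISA)/(SIB)/(PAT)`-labelled anchor in its intent and negative
evidence for every `(I-D)/(D-I)` one. Operationally this is computed by
deriving the shared attributes of each anchor's class pair, which the test
suite verifies to be equivalent to harvesting lattice concepts.

Conflict repair is a greedy fixpoint loop: while any negative set is
non-empty, take the anchor with the smallest conflict degree (ties: larger
support, then lexicographic identifier) and, against the first partner in
its negative set, eliminate the one with the greater conflict degree,
otherwise the smaller support. The tie-breaking chain beyond degree
comparison — eliminate the Type II anchor at a support tie, the
lexicographically greater identifier at a full tie — exists purely for
determinism; the first two comparisons carry the scientific content.
Evidence is recomputed over the survivors after every single elimination,
so degrees always describe the current anchor set, and termination is
guaranteed because every iteration removes one anchor. Repair precedes
screening; screening then removes Type II anchors with zero support while
retaining all Type I anchors, whose lexical certainty stands on its own.

Two readings were genuinely open and are fixed as follows. The Type II rule
accepts concepts whose simplified extent is *empty* (both strings generate
strictly smaller concepts): the class-origin condition over the full extent
is what carries the uniqueness argument, and the worked token-context
example requires the inclusive reading. And the ISA side of the mixed
`(I-D)`/`(D-I)` labels is strict (a class does not ISA-relate to itself):
the reflexive reading would mark every anchor class under its own conflict
column and contradicts the printed relation table.

## Degenerate inputs and numerical choices

* Empty-set derivations return the full dual set (the standard convention).
* Relation-type contexts keep only realized (non-empty) attribute columns;
  the printed cross-tables in the literature are fragments of exactly this
  construction.
* The top node of a positive relation lattice groups all classes with *no*
  marks (its intent is empty); it is skipped during extraction, since
  "sharing nothing" is not a commonality.
* Quantifiers are ignored when pairing restriction fillers (existential
  restrictions pair with universal ones) and are recorded in provenance
  only; biomedical ontologies systematically differ in which quantifier
  they use for the same modelling intent.
* All outputs are sorted on canonical keys (sorted extents for lattice
  nodes, IRI pairs for mappings), so identical inputs produce byte-identical
  alignment files.
* Complex candidates are reported with `review_required = TRUE` and are
  never fed into later steps; step 4 consumes only one-to-one mappings, and
  step 5 consumes all one-to-one mappings of the running alignment,
  including structural ones. Whether step 5 should see all extracted
  property mappings or a curated subset is left to the caller: all are used
  by default, and the "problematic" ones are extracted and flagged rather
  than suppressed, since deciding their validity is a domain-expert task.

## The synthetic-data generator

`random_ontology_pair()` emulates the situation the matcher is built for:
two ontologies sharing a core of identically named classes (the planted
ground truth, 30% of the smaller side by default) with a mirrored taxonomy
over that core, plus side-specific classes whose name tokens never co-occur
uniquely across the pair. Optional consistent disjointness between shared
roots (rate 0.05) and mirrored existential restrictions (rate 0.1) exercise
the validation and property machinery. Defaults of 40 classes per side keep
a full pipeline run well under a second.

What it does *not* emulate — and hence what passing recovery tests does not
show about real data: near-miss lexical variants (misleading token overlap
between non-equivalent classes), inconsistent structure between the sides,
synonym noise from external resources, multiple inheritance, and scale.
The named fixtures cover the first two qualitatively (shared-token
non-matches; the adipose-tissue disjointness conflict), but quantitative
precision/recall on real ontology pairs cannot be extrapolated from these
tests. Test problem sizes are deliberately small: random contexts up to
8×8 against the brute-force oracle (200 cases), random ontology pairs of
18–40 classes per side (100+ cases), chosen so the whole suite runs in
about a minute while still exercising every code path.

## Known limitations

* No incoherence detection or repair: the emitted alignment can make
  classes unsatisfiable when merged with the sources; conflicts are only
  repaired pairwise at the anchor level.
* Structural validation runs once, after step 1; mappings added by steps
  3–5 are not re-validated against each other.
* The OWL reader covers the subset the method consumes (named classes,
  subclass axioms, existential/universal restriction superclasses,
  intersection-style equivalences, disjointness, annotations); cardinality
  restrictions, nominals, property chains and individuals are out of scope.
* Property hierarchies (`subPropertyOf`) are ignored throughout.
* Evaluation scores one-to-one class mappings only; complex and property
  mappings are reported for manual review and excluded from precision and
  recall.
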