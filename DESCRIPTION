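Package: fcamapr
Title: Ontology Matching with Formal Concept Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns two OWL ontologies by incrementally building five formal
    contexts and extracting correspondences from their Galois sub-hierarchies:
    a token-based context yields lexical anchors between classes; a
    relation-based context over ISA, sibling, part-of and disjointness
    relations provides positive and negative structural evidence used to
    repair conflicts and screen anchors; a positive relation-based context
    discovers new one-to-one, one-to-group and group-to-group structural
    mappings; a property-based context aligns object properties through the
    axioms that connect mapped classes; and a restriction-based context over
    paired restriction fillers extracts extended one-to-one and complex
    correspondences. Includes a generic Formal Concept Analysis engine
    (derivation operators, full-lattice enumeration, Galois sub-hierarchy
    construction with simplified labelling), an OWL (RDF/XML) subset reader,
    OAEI-style alignment output and evaluation with an "Unknown" category,
    and seeded fixture generators with known ground-truth alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
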