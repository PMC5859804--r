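test_that("a toy OWL file loads with all axiom categories", {
  owl <- c(
    '<?xml version="1.0"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"',
    '         xmlns:owl="http://www.w3.org/2002/07/owl#">',
    '  <owl:ObjectProperty rdf:about="http://t#site"/>',
    '  <owl:Class rdf:about="http://t#A">',
    '    <rdfs:label>alpha</rdfs:label>',
    '    <rdfs:subClassOf rdf:resource="http://t#B"/>',
    '    <owl:disjointWith rdf:resource="http://t#C"/>',
    '  </owl:Class>',
    '  <owl:Class rdf:about="http://t#B">',
    '    <rdfs:subClassOf>',
    '      <owl:Restriction>',
    '        <owl:onProperty rdf:resource="http://t#site"/>',
    '        <owl:someValuesFrom rdf:resource="http://t#D"/>',
    '      </owl:Restriction>',
    '    </rdfs:subClassOf>',
    '  </owl:Class>',
    '  <owl:Class rdf:about="http://t#C"/>',
    '  <owl:Class rdf:about="http://t#D"/>',
    '</rdf:RDF>')
  path <- withr::local_tempfile(fileext = ".owl")
  writeLines(owl, path)
  onto <- load_ontology(path, tag = "T", quiet = TRUE)
  expect_identical(nrow(onto$isa), 1L)
  expect_identical(nrow(onto$disjoint), 1L)
  expect_identical(nrow(onto$restrictions), 1L)
  expect_identical(onto$restrictions$quantifier, "existential")
  expect_identical(onto$classes$primary_name[onto$classes$iri == "http://t#A"],
                   "alpha")
  expect_error(load_ontology(withr::local_tempfile(fileext = ".owl")),
               "cannot parse")
})

test_that("equivalence axioms decompose into named conjuncts plus restrictions", {
  owl <- c(
    '<?xml version="1.0"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"',
    '         xmlns:owl="http://www.w3.org/2002/07/owl#">',
    '  <owl:Class rdf:about="http://t#C">',
    '    <owl:equivalentClass>',
    '      <owl:Class>',
    '        <owl:intersectionOf rdf:parseType="Collection">',
    '          <rdf:Description rdf:about="http://t#D"/>',
    '          <owl:Restriction>',
    '            <owl:onProperty rdf:resource="http://t#r"/>',
    '            <owl:someValuesFrom rdf:resource="http://t#E"/>',
    '          </owl:Restriction>',
    '        </owl:intersectionOf>',
    '      </owl:Class>',
    '    </owl:equivalentClass>',
    '  </owl:Class>',
    '</rdf:RDF>')
  path <- withr::local_tempfile(fileext = ".owl")
  writeLines(owl, path)
  onto <- load_ontology(path, tag = "T", quiet = TRUE)
  expect_identical(onto$isa, data.frame(sub = "http://t#C",
                                        super = "http://t#D",
                                        stringsAsFactors = FALSE))
  expect_identical(onto$restrictions$subject, "http://t#C")
  expect_identical(onto$restrictions$property, "http://t#r")
  expect_identical(onto$restrictions$filler, "http://t#E")
})

test_that("closure queries: ancestors, partonomy propagation, siblings, disjointness", {
  onto <- toy_onto("T", c("a", "b", "c", "d", "e", "f", "w", "v"),
                   isa = list(c("a", "b"), c("b", "c"), c("d", "c"),
                              c("e", "a")),
                   partof = list(c("a", "w")),
                   disjoint = list(c("c", "f")))
  q <- closure_queries(onto)
  t <- function(n) toy_iri("T", n)
  expect_identical(q$isa_ancestors(t("a")), sort(c(t("b"), t("c"))))
  expect_identical(q$isa_descendants(t("c")),
                   sort(c(t("a"), t("b"), t("d"), t("e"))))
  # partonomy: part inherited by isa descendants, whole generalized upward
  expect_true(t("w") %in% q$partof_wholes(t("a")))
  expect_true(t("w") %in% q$partof_wholes(t("e")))   # e isa a, a partof w
  expect_identical(q$partof_wholes(t("b")), character(0))
  # siblings share a direct named superclass
  expect_identical(q$siblings(t("b")), t("d"))
  expect_identical(q$siblings(t("w")), character(0))
  # inherited disjointness: any subclass of c is disjoint-related to f
  expect_true(t("f") %in% q$disjoint_classes(t("a")))
  expect_true(t("a") %in% q$disjoint_classes(t("f")))
  expect_false(t("w") %in% q$disjoint_classes(t("f")))
})

test_that("partonomy propagates along the whole's ancestors and transitively", {
  onto <- toy_onto("T", c("p", "w", "W", "outer"),
                   isa = list(c("w", "W")),
                   partof = list(c("p", "w"), c("w", "outer")))
  q <- closure_queries(onto)
  t <- function(n) toy_iri("T", n)
  expect_setequal(q$partof_wholes(t("p")), c(t("w"), t("W"), t("outer")))
})

test_that("ISA cycles are fatal by default and collapsible by config", {
  expect_error(
    toy_onto("T", c("a", "b"), isa = list(c("a", "b"), c("b", "a"))),
    "ISA cycle")
  onto <- ontology("T",
                   data.frame(iri = c("x#a", "x#b", "x#c"),
                              primary_name = c("a", "b", "c"),
                              stringsAsFactors = FALSE),
                   isa = data.frame(sub = c("x#a", "x#b", "x#b"),
                                    super = c("x#b", "x#a", "x#c"),
                                    stringsAsFactors = FALSE),
                   cycle_policy = "collapse")
  expect_identical(sort(onto$classes$iri), c("x#a", "x#c"))
  expect_identical(onto$isa$sub, "x#a")
  expect_identical(onto$isa$super, "x#c")
})

test_that("closure monotonicity: adding an isa edge never shrinks ancestor sets", {
  base <- list(c("a", "b"), c("c", "d"))
  onto1 <- toy_onto("T", c("a", "b", "c", "d"), isa = base)
  onto2 <- toy_onto("T", c("a", "b", "c", "d"),
                    isa = c(base, list(c("b", "c"))))
  q1 <- closure_queries(onto1); q2 <- closure_queries(onto2)
  for (n in c("a", "b", "c", "d")) {
    expect_true(all(q1$isa_ancestors(toy_iri("T", n)) %in%
                      q2$isa_ancestors(toy_iri("T", n))))
  }
})

test_that("anonymous ancestors reproduce the liver-hemangioma closure on both sides", {
  fx <- make_fixture("hemangioma")
  s <- function(n) toy_iri("SNOMED", n)
  n <- function(n) toy_iri("NCI", n)
  aa1 <- anonymous_ancestors(fx$onto1, s("Hemangioma of liver"))
  expect_setequal(aa1$filler,
                  c(s("Vascular structure of liver"),
                    s("Blood vessel structure"),
                    s("Structure of cardiovascular system"),
                    s("Liver structure")))
  expect_true(all(aa1$quantifier == "existential"))
  expect_identical(
    aa1$provenance[aa1$filler == s("Vascular structure of liver")],
    "asserted")
  expect_identical(sum(aa1$provenance == "inferred"), 3L)
  aa2 <- anonymous_ancestors(fx$onto2, n("Hepatic Hemangioma"))
  expect_setequal(aa2$filler,
                  c(n("Blood Vessel"), n("Vascular System"),
                    n("Cardiovascular System"), n("Liver")))
  expect_true(all(aa2$quantifier == "universal"))
  # a class with no restrictions anywhere above it
  expect_identical(nrow(anonymous_ancestors(fx$onto1, s("Liver structure"))),
                   0L)
})

test_that("anonymous ancestors inherit from named ancestors and reach a fixed point", {
  onto <- toy_onto("T", c("child", "parent", "filler", "fillersup"),
                   isa = list(c("child", "parent"),
                              c("filler", "fillersup")),
                   properties = "rel",
                   restrictions = list(c("parent", "existential", "rel",
                                         "filler")))
  t <- function(x) toy_iri("T", x)
  aa <- anonymous_ancestors(onto, t("child"))   # R1 then R2
  expect_setequal(aa$filler, c(t("filler"), t("fillersup")))
  # fixed point: feeding the closure back as asserted axioms adds nothing
  onto2 <- onto
  onto2$restrictions <- rbind(onto2$restrictions,
                              aa[aa$provenance == "inferred", ])
  onto2$restrictions$subject <- c(onto$restrictions$subject,
                                  rep(t("child"), sum(aa$provenance == "inferred")))
  aa2 <- anonymous_ancestors(onto2, t("child"))
  expect_setequal(paste(aa2$property, aa2$filler),
                  paste(aa$property, aa$filler))
})

test_that("the internal dump format round-trips a loaded fixture", {
  fx <- make_fixture("ma_nci_relations")
  path <- withr::local_tempfile(fileext = ".txt")
  write_ontology_dump(fx$onto1, path)
  back <- read_ontology_dump(path)
  expect_identical(back$tag, fx$onto1$tag)
  expect_setequal(back$classes$iri, fx$onto1$classes$iri)
  expect_identical(back$isa[order(back$isa$sub, back$isa$super), ],
                   fx$onto1$isa[order(fx$onto1$isa$sub, fx$onto1$isa$super), ],
                   ignore_attr = TRUE)
  expect_identical(nrow(back$partof), nrow(fx$onto1$partof))
})

test_that("OWL writing and reloading preserves structure and lexicalizations", {
  td <- withr::local_tempdir()
  fx <- make_fixture("ma_nci_tokens", outdir = td)
  o2 <- load_ontology(fx$files[["onto2"]], tag = "NCI", quiet = TRUE)
  lx <- lexicalizations(o2)
  # the synonym-only class contributes exactly its synonym string
  expect_identical(
    lx$string[lx$iri == toy_iri("NCI", "Breast Fluid or Secretion")],
    "Mammary Gland Fluids and Secretions")
  fxh <- make_fixture("hemangioma", outdir = td)
  s1 <- load_ontology(fxh$files[["onto1"]], tag = "SNOMED", quiet = TRUE)
  expect_identical(nrow(s1$restrictions), 1L)
  expect_identical(nrow(s1$isa), 3L)
  aa <- anonymous_ancestors(s1, toy_iri("SNOMED", "Hemangioma of liver"))
  expect_identical(nrow(aa), 4L)
})
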