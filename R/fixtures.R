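#' Fixture and synthetic-data generators
#'
#' `make_fixture()` reifies the worked examples the method is specified on —
#' small anatomy / disease ontology pairs with known correct mappings — plus
#' a seeded random generator of synthetic ontology pairs with planted
#' ground-truth mappings. Named fixtures are fully deterministic; the
#' `"random"` fixture is deterministic given its seed.
#'
#' Available names:
#' * `"animals"` — the small animal/feature formal context (a context, not an
#'   ontology pair; returned under `$context`).
#' * `"ma_nci_tokens"` — mouse-anatomy vs cancer-thesaurus fragment whose
#'   token context exercises exact and unique-partial lexical matching.
#' * `"ma_nci_relations"` — fragment with taxonomy, partonomy and a
#'   disjointness conflict, plus its lexical anchors (under `$anchors`).
#' * `"ma_nci_combined"` — the union of the previous two with bridging
#'   superclasses and a small token lexicon (under `$lexicon`), suitable for
#'   running steps 1–2 end to end.
#' * `"suprarenal"` — one-to-group granularity difference.
#' * `"sacral"` — group-to-group mouse/human vertebra difference.
#' * `"snomed_nci_properties"` — clinical-terms vs cancer-thesaurus fragment
#'   with object properties and restriction axioms; its one-to-one class
#'   mappings are under `$mappings`.
#' * `"hemangioma"` — the liver-hemangioma anchor with four anonymous
#'   ancestors per side (under `$anchors`, `$property_mappings`).
#' * `"fig6_restriction"` — a multi-anchor cardiovascular/liver fixture whose
#'   restriction lattice yields extended one-to-one matches and a complex
#'   candidate.
#' * `"random"` — seeded synthetic pair; see [random_ontology_pair()].
#'
#' @param name fixture identifier (see above).
#' @param seed integer seed (used by `"random"` only).
#' @param outdir optional directory: when given, the ontology pair is written
#'   as OWL (`<name>_1.owl`, `<name>_2.owl`) and the ground truth as
#'   Alignment RDF (`<name>_reference.rdf`), and the paths are returned under
#'   `$files`.
#' @param params named list of generator parameters for `"random"`
#'   (`n1`, `n2`, `overlap`, `depth`, `disjoint_rate`, `restriction_rate`).
#' @return A list with (depending on the fixture) `onto1`, `onto2`,
#'   `ground_truth` (data frame `class1`, `class2`), and the extras noted
#'   above.
#' @export
make_fixture <- function(name, seed = 1L, outdir = NULL, params = list()) {
  fx <- switch(name,
    animals = fixture_animals(),
    ma_nci_tokens = fixture_ma_nci_tokens(),
    ma_nci_relations = fixture_ma_nci_relations(),
    ma_nci_combined = fixture_ma_nci_combined(),
    suprarenal = fixture_suprarenal(),
    sacral = fixture_sacral(),
    snomed_nci_properties = fixture_snomed_nci_properties(),
    hemangioma = fixture_hemangioma(),
    fig6_restriction = fixture_fig6_restriction(),
    random = do.call(random_ontology_pair, c(list(seed = seed), params)),
    stop("unknown fixture name: ", name)
  )
  if (!is.null(outdir) && !is.null(fx$onto1)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    f1 <- file.path(outdir, paste0(name, "_1.owl"))
    f2 <- file.path(outdir, paste0(name, "_2.owl"))
    fr <- file.path(outdir, paste0(name, "_reference.rdf"))
    write_owl(fx$onto1, f1,
              base_iri = paste0("http://fcamapr.example/", fx$onto1$tag, "#"))
    write_owl(fx$onto2, f2,
              base_iri = paste0("http://fcamapr.example/", fx$onto2$tag, "#"))
    write_alignment_rdf(fx$ground_truth, fr)
    fx$files <- c(onto1 = f1, onto2 = f2, reference = fr)
  }
  fx
}

fx_iri <- function(tag, name) {
  paste0("http://fcamapr.example/", tag, "#",
         gsub("(^_)|(_$)", "", gsub("[^A-Za-z0-9]+", "_", name)))
}

# Compact ontology builder: classes is a character vector of names (the label
# defaults to the name); lex_extra overrides per-class lexicalizations.
fx_onto <- function(tag, classes, isa = NULL, partof = NULL, disjoint = NULL,
                    properties = NULL, restrictions = NULL,
                    no_label = character(0), synonyms = list()) {
  iri <- function(n) fx_iri(tag, n)
  cls <- data.frame(iri = iri(classes), primary_name = classes,
                    stringsAsFactors = FALSE)
  lab <- setdiff(classes, no_label)
  lex <- data.frame(iri = iri(lab), string = lab, kind = "label",
                    stringsAsFactors = FALSE)
  for (cn in names(synonyms)) {
    lex <- rbind(lex, data.frame(iri = iri(cn), string = synonyms[[cn]],
                                 kind = "synonym", stringsAsFactors = FALSE))
  }
  pairs_df <- function(x, cols) {
    if (is.null(x)) return(NULL)
    m <- do.call(rbind, x)
    setNames(data.frame(iri(m[, 1]), iri(m[, 2]), stringsAsFactors = FALSE),
             cols)
  }
  props <- if (is.null(properties)) NULL else
    data.frame(iri = iri(properties), name = properties,
               stringsAsFactors = FALSE)
  restr <- if (is.null(restrictions)) NULL else {
    m <- do.call(rbind, restrictions)  # subject, quantifier, property, filler
    data.frame(subject = iri(m[, 1]), quantifier = m[, 2],
               property = iri(m[, 3]), filler = iri(m[, 4]),
               provenance = "asserted", stringsAsFactors = FALSE)
  }
  ontology(tag, cls, lex = lex, properties = props,
           isa = pairs_df(isa, c("sub", "super")),
           partof = pairs_df(partof, c("part", "whole")),
           disjoint = pairs_df(disjoint, c("a", "b")),
           restrictions = restr)
}

fixture_animals <- function() {
  ctx <- formal_context(
    objects = c("Elephant", "Dolphin", "Porpoise", "Hawk", "Octopus"),
    attributes = c("Vertebrate", "Mammal", "Flying", "Aquatic", "Carnivorous"),
    incidence = rbind(
      c("Elephant", "Vertebrate"), c("Elephant", "Mammal"),
      c("Dolphin", "Vertebrate"), c("Dolphin", "Mammal"),
      c("Dolphin", "Aquatic"), c("Dolphin", "Carnivorous"),
      c("Porpoise", "Vertebrate"), c("Porpoise", "Mammal"),
      c("Porpoise", "Aquatic"), c("Porpoise", "Carnivorous"),
      c("Hawk", "Vertebrate"), c("Hawk", "Flying"), c("Hawk", "Carnivorous"),
      c("Octopus", "Aquatic"), c("Octopus", "Carnivorous")))
  list(context = ctx)
}

fx_gt <- function(tag1, tag2, pairs) {
  m <- do.call(rbind, pairs)
  data.frame(class1 = fx_iri(tag1, m[, 1]), class2 = fx_iri(tag2, m[, 2]),
             stringsAsFactors = FALSE)
}

fixture_ma_nci_tokens <- function() {
  ma <- fx_onto("MA", c("palatine gland", "adrenal gland zona fasciculata",
                        "adrenal gland zona reticularis",
                        "mammary gland fluid/secretion"))
  nci <- fx_onto("NCI", c("Palatine Salivary Gland", "Fasciculata Zone",
                          "Reticularis Zone", "Breast Fluid or Secretion"),
                 no_label = "Breast Fluid or Secretion",
                 synonyms = list("Breast Fluid or Secretion" =
                                   "Mammary Gland Fluids and Secretions"))
  gt <- fx_gt("MA", "NCI", list(
    c("palatine gland", "Palatine Salivary Gland"),
    c("adrenal gland zona fasciculata", "Fasciculata Zone"),
    c("adrenal gland zona reticularis", "Reticularis Zone"),
    c("mammary gland fluid/secretion", "Breast Fluid or Secretion")))
  list(onto1 = ma, onto2 = nci, ground_truth = gt)
}

fixture_ma_nci_relations <- function() {
  ma <- fx_onto("MA",
    c("ligament", "periodontal ligament", "auricular ligament",
      "adipose tissue", "larynx ligament", "larynx", "organ system"),
    isa = list(c("ligament", "organ system"),
               c("adipose tissue", "organ system"),
               c("periodontal ligament", "ligament"),
               c("auricular ligament", "ligament"),
               c("larynx ligament", "ligament")),
    partof = list(c("larynx ligament", "larynx")))
  nci <- fx_onto("NCI",
    c("Ligament", "Periodontium", "Broad Ligament", "Adipose Tissue",
      "Laryngeal Ligament", "Larynx", "Organ System"),
    isa = list(c("Periodontium", "Ligament"),
               c("Broad Ligament", "Ligament"),
               c("Laryngeal Ligament", "Ligament")),
    partof = list(c("Laryngeal Ligament", "Larynx")),
    disjoint = list(c("Ligament", "Organ System"),
                    c("Adipose Tissue", "Organ System")))
  anchor <- function(n1, n2, type) data.frame(
    class1 = fx_iri("MA", n1), class2 = fx_iri("NCI", n2), type = type,
    provenance = "fixture", stringsAsFactors = FALSE)
  anchors <- rbind(
    anchor("ligament", "Ligament", "TypeI"),
    anchor("organ system", "Organ System", "TypeI"),
    anchor("adipose tissue", "Adipose Tissue", "TypeI"),
    anchor("larynx ligament", "Laryngeal Ligament", "TypeI"),
    anchor("larynx", "Larynx", "TypeI"),
    anchor("periodontal ligament", "Periodontium", "TypeII"))
  gt <- fx_gt("MA", "NCI", list(
    c("ligament", "Ligament"), c("adipose tissue", "Adipose Tissue"),
    c("larynx ligament", "Laryngeal Ligament"), c("larynx", "Larynx"),
    c("periodontal ligament", "Periodontium")))
  list(onto1 = ma, onto2 = nci, ground_truth = gt, anchors = anchors)
}

fixture_ma_nci_combined <- function() {
  ma <- fx_onto("MA",
    c("palatine gland", "adrenal gland zona fasciculata",
      "adrenal gland zona reticularis", "mammary gland fluid/secretion",
      "adrenal gland", "salivary gland", "sublingual gland",
      "ligament", "periodontal ligament", "auricular ligament",
      "adipose tissue", "larynx ligament", "larynx", "organ system"),
    isa = list(c("adrenal gland zona fasciculata", "adrenal gland"),
               c("adrenal gland zona reticularis", "adrenal gland"),
               c("palatine gland", "salivary gland"),
               c("sublingual gland", "salivary gland"),
               c("ligament", "organ system"),
               c("adipose tissue", "organ system"),
               c("periodontal ligament", "ligament"),
               c("auricular ligament", "ligament"),
               c("larynx ligament", "ligament")),
    partof = list(c("larynx ligament", "larynx")))
  nci <- fx_onto("NCI",
    c("Palatine Salivary Gland", "Fasciculata Zone", "Reticularis Zone",
      "Breast Fluid or Secretion", "Adrenal Gland", "Salivary Gland",
      "Sublingual Gland",
      "Ligament", "Periodontium", "Broad Ligament", "Adipose Tissue",
      "Laryngeal Ligament", "Larynx", "Organ System"),
    no_label = "Breast Fluid or Secretion",
    synonyms = list("Breast Fluid or Secretion" =
                      "Mammary Gland Fluids and Secretions"),
    isa = list(c("Fasciculata Zone", "Adrenal Gland"),
               c("Reticularis Zone", "Adrenal Gland"),
               c("Palatine Salivary Gland", "Salivary Gland"),
               c("Sublingual Gland", "Salivary Gland"),
               c("Periodontium", "Ligament"),
               c("Broad Ligament", "Ligament"),
               c("Laryngeal Ligament", "Ligament")),
    partof = list(c("Laryngeal Ligament", "Larynx")),
    disjoint = list(c("Ligament", "Organ System"),
                    c("Adipose Tissue", "Organ System")))
  lexicon <- token_lexicon(c(laryngeal = "larynx",
                             periodontium = "periodontal"))
  gt <- fx_gt("MA", "NCI", list(
    c("palatine gland", "Palatine Salivary Gland"),
    c("adrenal gland zona fasciculata", "Fasciculata Zone"),
    c("adrenal gland zona reticularis", "Reticularis Zone"),
    c("mammary gland fluid/secretion", "Breast Fluid or Secretion"),
    c("adrenal gland", "Adrenal Gland"),
    c("salivary gland", "Salivary Gland"),
    c("sublingual gland", "Sublingual Gland"),
    c("ligament", "Ligament"), c("adipose tissue", "Adipose Tissue"),
    c("larynx ligament", "Laryngeal Ligament"), c("larynx", "Larynx"),
    c("periodontal ligament", "Periodontium")))
  list(onto1 = ma, onto2 = nci, ground_truth = gt, lexicon = lexicon)
}

fixture_suprarenal <- function() {
  ma <- fx_onto("MA",
    c("suprarenal vein", "inferior suprarenal vein", "adrenal gland"),
    isa = list(c("inferior suprarenal vein", "suprarenal vein")),
    partof = list(c("inferior suprarenal vein", "adrenal gland")))
  nci <- fx_onto("NCI",
    c("Suprarenal Vein", "Left Suprarenal Vein", "Right Suprarenal Vein",
      "Adrenal Gland"),
    isa = list(c("Left Suprarenal Vein", "Suprarenal Vein"),
               c("Right Suprarenal Vein", "Suprarenal Vein")),
    partof = list(c("Left Suprarenal Vein", "Adrenal Gland"),
                  c("Right Suprarenal Vein", "Adrenal Gland")))
  gt <- fx_gt("MA", "NCI", list(
    c("suprarenal vein", "Suprarenal Vein"),
    c("adrenal gland", "Adrenal Gland")))
  list(onto1 = ma, onto2 = nci, ground_truth = gt)
}

fixture_sacral <- function() {
  mk <- function(tag, parent, children) {
    fx_onto(tag, c(parent, children),
            isa = lapply(children, function(ch) c(ch, parent)))
  }
  ma <- mk("MA", "sacral vertebra", paste("sacral vertebra", 1:4))
  nci <- mk("NCI", "Sacral Vertebra", paste0("S", 1:5, " Vertebra"))
  gt <- fx_gt("MA", "NCI", list(c("sacral vertebra", "Sacral Vertebra")))
  list(onto1 = ma, onto2 = nci, ground_truth = gt)
}

fixture_snomed_nci_properties <- function() {
  sn <- fx_onto("SNOMED",
    c("Benign neoplasm of buccal mucosa", "Buccal mucosa",
      "Synovioma benign", "Soft tissues",
      "Phocomelia of upper limb NOS", "Upper extremity part",
      "Bowenoid papulosis", "Human papilloma virus infection",
      "Insulin coma", "Hypoglycemia", "Laparoscopy", "Endoscope device"),
    properties = c("Finding site", "Due to", "Using device"),
    restrictions = list(
      c("Benign neoplasm of buccal mucosa", "existential", "Finding site",
        "Buccal mucosa"),
      c("Synovioma benign", "existential", "Finding site", "Soft tissues"),
      c("Phocomelia of upper limb NOS", "existential", "Finding site",
        "Upper extremity part"),
      c("Bowenoid papulosis", "existential", "Due to",
        "Human papilloma virus infection"),
      c("Insulin coma", "existential", "Due to", "Hypoglycemia"),
      c("Laparoscopy", "existential", "Using device", "Endoscope device")))
  nci <- fx_onto("NCI",
    c("Benign Buccal Mucosa Neoplasm", "Buccal Mucosa",
      "Benign Synovial Neoplasm", "Soft Tissue",
      "Phocomelia of the Upper Limb", "Upper Extremity Part",
      "Bowenoid Papulosis", "Human Papilloma Virus Infection",
      "Insulin Coma", "Hypoglycemia", "Laparoscopy", "Endoscope"),
    properties = c("Disease Has Primary Anatomic Site",
                   "Disease May Have Associated Disease"),
    restrictions = list(
      c("Benign Buccal Mucosa Neoplasm", "universal",
        "Disease Has Primary Anatomic Site", "Buccal Mucosa"),
      c("Phocomelia of the Upper Limb", "universal",
        "Disease Has Primary Anatomic Site", "Upper Extremity Part"),
      c("Bowenoid Papulosis", "universal",
        "Disease May Have Associated Disease",
        "Human Papilloma Virus Infection")))
  pair <- list(
    c("Benign neoplasm of buccal mucosa", "Benign Buccal Mucosa Neoplasm"),
    c("Buccal mucosa", "Buccal Mucosa"),
    c("Synovioma benign", "Benign Synovial Neoplasm"),
    c("Soft tissues", "Soft Tissue"),
    c("Phocomelia of upper limb NOS", "Phocomelia of the Upper Limb"),
    c("Upper extremity part", "Upper Extremity Part"),
    c("Bowenoid papulosis", "Bowenoid Papulosis"),
    c("Human papilloma virus infection", "Human Papilloma Virus Infection"),
    c("Insulin coma", "Insulin Coma"),
    c("Hypoglycemia", "Hypoglycemia"),
    c("Laparoscopy", "Laparoscopy"),
    c("Endoscope device", "Endoscope"))
  gt <- fx_gt("SNOMED", "NCI", pair)
  mappings <- gt
  mappings$type <- "TypeI"; mappings$provenance <- "fixture"
  prop_gt <- data.frame(
    property1 = fx_iri("SNOMED", c("Finding site", "Due to")),
    property2 = fx_iri("NCI", c("Disease Has Primary Anatomic Site",
                                "Disease May Have Associated Disease")),
    stringsAsFactors = FALSE)
  list(onto1 = sn, onto2 = nci, ground_truth = gt, mappings = mappings,
       property_ground_truth = prop_gt)
}

fixture_hemangioma <- function() {
  sn <- fx_onto("SNOMED",
    c("Hemangioma of liver", "Vascular structure of liver",
      "Blood vessel structure", "Structure of cardiovascular system",
      "Liver structure"),
    isa = list(c("Vascular structure of liver", "Blood vessel structure"),
               c("Blood vessel structure",
                 "Structure of cardiovascular system"),
               c("Vascular structure of liver", "Liver structure")),
    properties = "Finding site",
    restrictions = list(c("Hemangioma of liver", "existential",
                          "Finding site", "Vascular structure of liver")))
  nci <- fx_onto("NCI",
    c("Hepatic Hemangioma", "Blood Vessel", "Vascular System",
      "Cardiovascular System", "Liver"),
    isa = list(c("Blood Vessel", "Vascular System"),
               c("Vascular System", "Cardiovascular System")),
    properties = "Disease Has Associated Anatomic Site",
    restrictions = list(
      c("Hepatic Hemangioma", "universal",
        "Disease Has Associated Anatomic Site", "Blood Vessel"),
      c("Hepatic Hemangioma", "universal",
        "Disease Has Associated Anatomic Site", "Liver")))
  anchors <- data.frame(
    class1 = fx_iri("SNOMED", "Hemangioma of liver"),
    class2 = fx_iri("NCI", "Hepatic Hemangioma"),
    type = "TypeII", provenance = "fixture", stringsAsFactors = FALSE)
  prop_maps <- data.frame(
    property1 = fx_iri("SNOMED", "Finding site"),
    property2 = fx_iri("NCI", "Disease Has Associated Anatomic Site"),
    provenance = "fixture", stringsAsFactors = FALSE)
  gt <- fx_gt("SNOMED", "NCI",
              list(c("Hemangioma of liver", "Hepatic Hemangioma")))
  list(onto1 = sn, onto2 = nci, ground_truth = gt, anchors = anchors,
       property_mappings = prop_maps)
}

fixture_fig6_restriction <- function() {
  sn <- fx_onto("SNOMED",
    c("Hemangioma", "Hemangioma of liver", "Vascular structure of liver",
      "Blood vessel structure", "Structure of cardiovascular system",
      "Liver structure", "Pericarditis", "Structure of visceral pericardium",
      "Heart structure", "Atrial flutter", "Atrial structure",
      "Vasculitis", "Hepatitis", "Arteritis", "Arterial structure",
      "Hepatomegaly", "Digestive organ structure"),
    isa = list(
      c("Hemangioma of liver", "Hemangioma"),
      c("Vascular structure of liver", "Blood vessel structure"),
      c("Blood vessel structure", "Structure of cardiovascular system"),
      c("Vascular structure of liver", "Liver structure"),
      c("Structure of visceral pericardium", "Heart structure"),
      c("Heart structure", "Structure of cardiovascular system"),
      c("Atrial structure", "Heart structure")),
    properties = "Finding site",
    restrictions = list(
      c("Hemangioma of liver", "existential", "Finding site",
        "Vascular structure of liver"),
      c("Pericarditis", "existential", "Finding site",
        "Structure of visceral pericardium"),
      c("Atrial flutter", "existential", "Finding site", "Atrial structure"),
      c("Vasculitis", "existential", "Finding site",
        "Blood vessel structure"),
      c("Hepatitis", "existential", "Finding site", "Liver structure"),
      c("Arteritis", "existential", "Finding site", "Arterial structure"),
      c("Hepatomegaly", "existential", "Finding site",
        "Digestive organ structure")))
  nci <- fx_onto("NCI",
    c("Hemangioma", "Hepatic Hemangioma", "Blood Vessel", "Vascular System",
      "Cardiovascular System", "Liver", "Pericarditis", "Epicardium",
      "Heart", "Atrial Flutter", "Cardiac Atrium", "Vasculitis",
      "Vascular Tissue", "Hepatitis", "Hepatobiliary System", "Arteritis",
      "Hepatomegaly"),
    isa = list(
      c("Hepatic Hemangioma", "Hemangioma"),
      c("Blood Vessel", "Vascular System"),
      c("Vascular System", "Cardiovascular System"),
      c("Epicardium", "Heart"),
      c("Heart", "Cardiovascular System"),
      c("Cardiac Atrium", "Heart")),
    properties = "Disease Has Associated Anatomic Site",
    restrictions = list(
      c("Hepatic Hemangioma", "universal",
        "Disease Has Associated Anatomic Site", "Blood Vessel"),
      c("Hepatic Hemangioma", "universal",
        "Disease Has Associated Anatomic Site", "Liver"),
      c("Pericarditis", "universal",
        "Disease Has Associated Anatomic Site", "Epicardium"),
      c("Atrial Flutter", "universal",
        "Disease Has Associated Anatomic Site", "Cardiac Atrium"),
      c("Vasculitis", "universal",
        "Disease Has Associated Anatomic Site", "Blood Vessel"),
      c("Vasculitis", "universal",
        "Disease Has Associated Anatomic Site", "Vascular Tissue"),
      c("Hepatitis", "universal",
        "Disease Has Associated Anatomic Site", "Liver"),
      c("Hepatitis", "universal",
        "Disease Has Associated Anatomic Site", "Hepatobiliary System"),
      c("Arteritis", "universal",
        "Disease Has Associated Anatomic Site", "Blood Vessel"),
      c("Hepatomegaly", "universal",
        "Disease Has Associated Anatomic Site", "Liver")))
  anchor <- function(n1, n2, type) data.frame(
    class1 = fx_iri("SNOMED", n1), class2 = fx_iri("NCI", n2), type = type,
    provenance = "fixture", stringsAsFactors = FALSE)
  anchors <- rbind(
    anchor("Hemangioma", "Hemangioma", "TypeI"),
    anchor("Hemangioma of liver", "Hepatic Hemangioma", "structural"),
    anchor("Pericarditis", "Pericarditis", "TypeI"),
    anchor("Atrial flutter", "Atrial Flutter", "TypeI"),
    anchor("Vasculitis", "Vasculitis", "TypeI"),
    anchor("Hepatitis", "Hepatitis", "TypeI"),
    anchor("Arteritis", "Arteritis", "TypeI"),
    anchor("Hepatomegaly", "Hepatomegaly", "TypeI"),
    anchor("Heart structure", "Heart", "TypeII"),
    anchor("Structure of cardiovascular system", "Cardiovascular System",
           "TypeII"))
  prop_maps <- data.frame(
    property1 = fx_iri("SNOMED", "Finding site"),
    property2 = fx_iri("NCI", "Disease Has Associated Anatomic Site"),
    provenance = "fixture", stringsAsFactors = FALSE)
  gt <- fx_gt("SNOMED", "NCI", list(
    c("Hemangioma", "Hemangioma"),
    c("Hemangioma of liver", "Hepatic Hemangioma"),
    c("Pericarditis", "Pericarditis"),
    c("Atrial flutter", "Atrial Flutter"),
    c("Vasculitis", "Vasculitis"),
    c("Hepatitis", "Hepatitis"),
    c("Arteritis", "Arteritis"),
    c("Hepatomegaly", "Hepatomegaly"),
    c("Heart structure", "Heart"),
    c("Structure of cardiovascular system", "Cardiovascular System"),
    c("Structure of visceral pericardium", "Epicardium"),
    c("Atrial structure", "Cardiac Atrium")))
  list(onto1 = sn, onto2 = nci, ground_truth = gt, anchors = anchors,
       property_mappings = prop_maps)
}

#' Generate a random ontology pair with planted mappings
#'
#' Emulates two overlapping domain ontologies: a shared core of classes
#' present in both (identical multi-token names — the planted ground truth),
#' plus side-specific classes whose name tokens never co-occur uniquely
#' across the pair. The taxonomy over the shared core is mirrored on both
#' sides (consistent structure); side-specific classes attach at random.
#' Optional consistent disjointness between shared top-level classes and
#' mirrored existential restrictions exercise steps 2 and 4–5 machinery.
#'
#' @param seed integer seed.
#' @param n1,n2 class counts of the two sides (shared core included).
#' @param overlap fraction of `min(n1, n2)` planted as shared classes.
#' @param disjoint_rate probability of a disjointness axiom between any two
#'   shared root classes (asserted on both sides).
#' @param restriction_rate probability that a shared class carries a mirrored
#'   existential restriction towards another shared class.
#' @return As [make_fixture()]: `onto1`, `onto2`, `ground_truth`.
#' @export
random_ontology_pair <- function(seed = 1L, n1 = 40, n2 = 40, overlap = 0.3,
                                 disjoint_rate = 0.05,
                                 restriction_rate = 0.1) {
  stopifnot(n1 >= 4, n2 >= 4, overlap > 0, overlap <= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  n_shared <- max(2L, round(overlap * min(n1, n2)))
  shared_names <- sprintf("shared%02d structure", seq_len(n_shared))
  # mirrored taxonomy over the shared core: class i attaches under a random
  # earlier shared class (or stays a root)
  shared_isa <- list()
  for (i in seq_len(n_shared)[-1]) {
    if (stats::runif(1) < 0.7) {
      p <- sample.int(i - 1L, 1L)
      shared_isa[[length(shared_isa) + 1L]] <-
        c(shared_names[i], shared_names[p])
    }
  }
  roots <- setdiff(shared_names,
                   vapply(shared_isa, `[`, character(1), 1))
  disjoint <- list()
  if (length(roots) >= 2 && disjoint_rate > 0) {
    cmb <- utils::combn(roots, 2)
    for (k in seq_len(ncol(cmb))) {
      if (stats::runif(1) < disjoint_rate)
        disjoint[[length(disjoint) + 1L]] <- cmb[, k]
    }
  }
  restr <- list()
  if (restriction_rate > 0 && n_shared >= 2) {
    for (i in seq_len(n_shared)) {
      if (stats::runif(1) < restriction_rate) {
        j <- sample(setdiff(seq_len(n_shared), i), 1L)
        restr[[length(restr) + 1L]] <-
          c(shared_names[i], "existential", "relates to", shared_names[j])
      }
    }
  }

  side <- function(tag, n, side_prefix) {
    n_extra <- n - n_shared
    extra <- if (n_extra > 0)
      sprintf("%s%03d structure", side_prefix, seq_len(n_extra))
    else character(0)
    all_names <- c(shared_names, extra)
    isa <- shared_isa
    for (i in seq_along(extra)) {
      if (stats::runif(1) < 0.8) {
        # attach only to shared or earlier side classes: keeps the graph acyclic
        cand <- c(shared_names, extra[seq_len(i - 1L)])
        p <- cand[sample.int(length(cand), 1L)]
        isa[[length(isa) + 1L]] <- c(extra[i], p)
      }
    }
    fx_onto(tag, all_names, isa = isa,
            disjoint = if (length(disjoint)) disjoint else NULL,
            properties = if (length(restr)) "relates to" else NULL,
            restrictions = if (length(restr)) restr else NULL)
  }
  # side taxonomies are sampled independently, so extra classes may attach
  # under shared classes on either side without breaking consistency
  o1 <- side("O1", n1, "left")
  o2 <- side("O2", n2, "right")
  gt <- data.frame(class1 = fx_iri("O1", shared_names),
                   class2 = fx_iri("O2", shared_names),
                   stringsAsFactors = FALSE)
  list(onto1 = o1, onto2 = o2, ground_truth = gt)
}
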