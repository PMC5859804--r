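#' Load configuration for OWL ingestion
#'
#' @param label_iris annotation property IRIs read as labels.
#' @param synonym_iris annotation property IRIs read as synonyms.
#' @param partof_iris property IRIs treated as PART-OF in addition to any
#'   property whose local name matches `part_of` / `part of`
#'   (case-insensitively).
#' @param cycle_policy `"fatal"` or `"collapse"` for ISA cycles.
#' @return A named list of configuration values.
#' @export
load_config <- function(label_iris = "http://www.w3.org/2000/01/rdf-schema#label",
                        synonym_iris = c(
                          "http://www.geneontology.org/formats/oboInOwl#hasRelatedSynonym",
                          "http://www.geneontology.org/formats/oboInOwl#hasExactSynonym"),
                        partof_iris = character(0),
                        cycle_policy = "fatal") {
  list(label_iris = label_iris, synonym_iris = synonym_iris,
       partof_iris = partof_iris, cycle_policy = cycle_policy)
}

owl_ns <- c(
  rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl = "http://www.w3.org/2002/07/owl#",
  obo = "http://www.geneontology.org/formats/oboInOwl#"
)

local_name <- function(iri) sub(".*[#/]", "", iri)
pretty_name <- function(iri) gsub("_", " ", local_name(iri), fixed = TRUE)

is_partof_property <- function(iri, config) {
  iri %in% config$partof_iris ||
    grepl("^(UNDEFINED_)?part[ _]?of$", local_name(iri), ignore.case = TRUE)
}

node_iri <- function(node) {
  iri <- xml2::xml_attr(node, "about")
  if (is.na(iri)) iri <- xml2::xml_attr(node, "resource")
  iri
}

#' Load an OWL (RDF/XML) ontology
#'
#' Reads the OWL subset the matching method consumes: named classes with
#' label/synonym annotations, named-class subclass axioms, quantified
#' restriction superclasses (existential and universal), equivalent-class
#' axioms with intersection conjuncts (decomposed into subclass axioms and
#' restrictions), disjointness axioms, and object properties. Restrictions on
#' a PART-OF property become partonomy edges rather than restriction axioms.
#' A load report with per-category counts is emitted as a message.
#'
#' @param path path to an RDF/XML OWL file.
#' @param config a [load_config()] list.
#' @param tag source tag for the loaded ontology (default: file name stem).
#' @param quiet suppress the load report.
#' @return An [ontology()] object.
#' @export
load_ontology <- function(path, config = load_config(), tag = NULL,
                          quiet = FALSE) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse OWL file '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(tag)) tag <- tools::file_path_sans_ext(basename(path))
  full_iri <- function(node) xml2::xml_attr(node, "about")

  classes <- xml2::xml_find_all(doc, "/rdf:RDF/owl:Class[@rdf:about]")
  props <- xml2::xml_find_all(doc, "/rdf:RDF/owl:ObjectProperty[@rdf:about]")

  cl_iri <- vapply(classes, full_iri, character(1))
  keep <- !duplicated(cl_iri)
  classes <- classes[keep]; cl_iri <- cl_iri[keep]

  lex <- list(); isa <- list(); partof <- list(); disjoint <- list()
  restrictions <- list(); extra_props <- character(0)
  warn_ann <- character(0)

  ann_value <- function(node) xml2::xml_text(node)

  read_restriction <- function(rnode, subject) {
    onprop <- xml2::xml_find_first(rnode, "./owl:onProperty")
    prop <- node_iri(onprop)
    if (is.na(prop)) {
      nested <- xml2::xml_find_first(rnode, "./owl:onProperty/owl:ObjectProperty")
      prop <- if (inherits(nested, "xml_missing")) NA_character_ else full_iri(nested)
    }
    some <- xml2::xml_find_first(rnode, "./owl:someValuesFrom")
    allv <- xml2::xml_find_first(rnode, "./owl:allValuesFrom")
    quant <- NULL; fnode <- NULL
    if (!inherits(some, "xml_missing")) { quant <- "existential"; fnode <- some }
    if (!inherits(allv, "xml_missing")) { quant <- "universal"; fnode <- allv }
    if (is.na(prop) || is.null(quant)) return(NULL)
    filler <- node_iri(fnode)
    if (is.na(filler)) {
      nested <- xml2::xml_find_first(fnode, "./owl:Class")
      filler <- if (inherits(nested, "xml_missing")) NA_character_ else full_iri(nested)
    }
    if (is.na(filler)) return(NULL)
    list(subject = subject, quantifier = quant, property = prop,
         filler = filler)
  }

  add_axiom <- function(ax) {
    if (is.null(ax)) return()
    if (is_partof_property(ax$property, config)) {
      partof[[length(partof) + 1L]] <<- c(ax$subject, ax$filler)
    } else {
      restrictions[[length(restrictions) + 1L]] <<-
        c(ax$subject, ax$quantifier, ax$property, ax$filler, "asserted")
      extra_props <<- union(extra_props, ax$property)
    }
  }

  for (i in seq_along(classes)) {
    cnode <- classes[[i]]; iri <- cl_iri[i]
    for (child in xml2::xml_children(cnode)) {
      prop_iri <- child_property_iri(child)
      if (prop_iri %in% config$label_iris) {
        lex[[length(lex) + 1L]] <- c(iri, ann_value(child), "label")
      } else if (prop_iri %in% config$synonym_iris) {
        lex[[length(lex) + 1L]] <- c(iri, ann_value(child), "synonym")
      } else if (prop_iri == paste0(owl_ns[["rdfs"]], "subClassOf")) {
        res <- xml2::xml_attr(child, "resource")
        if (!is.na(res)) {
          isa[[length(isa) + 1L]] <- c(iri, res)
        } else {
          rnode <- xml2::xml_find_first(child, "./owl:Restriction")
          if (!inherits(rnode, "xml_missing"))
            add_axiom(read_restriction(rnode, iri))
        }
      } else if (prop_iri == paste0(owl_ns[["owl"]], "disjointWith")) {
        res <- node_iri(child)
        if (!is.na(res)) disjoint[[length(disjoint) + 1L]] <- c(iri, res)
      } else if (prop_iri == paste0(owl_ns[["owl"]], "equivalentClass")) {
        # decompose C == D1 ∩ D2 ∩ ... into subclass conjuncts
        members <- xml2::xml_find_all(
          child, ".//owl:intersectionOf/*")
        if (!length(members)) {
          res <- node_iri(child)
          if (!is.na(res)) isa[[length(isa) + 1L]] <- c(iri, res)
        }
        for (m in members) {
          if (xml2::xml_name(m) == "Restriction") {
            add_axiom(read_restriction(m, iri))
          } else {
            res <- node_iri(m)
            if (!is.na(res)) isa[[length(isa) + 1L]] <- c(iri, res)
          }
        }
      }
    }
  }

  prop_iri_v <- vapply(props, full_iri, character(1))
  prop_iri_v <- union(prop_iri_v, extra_props)
  prop_iri_v <- prop_iri_v[!vapply(prop_iri_v, is_partof_property,
                                   logical(1), config = config)]
  prop_df <- if (length(prop_iri_v))
    data.frame(iri = prop_iri_v, name = pretty_name(prop_iri_v),
               stringsAsFactors = FALSE) else NULL

  mk <- function(lst, cols) {
    if (!length(lst)) return(NULL)
    setNames(as.data.frame(do.call(rbind, lst), stringsAsFactors = FALSE), cols)
  }
  lex_df <- mk(lex, c("iri", "string", "kind"))
  isa_df <- mk(isa, c("sub", "super"))
  partof_df <- mk(partof, c("part", "whole"))
  disjoint_df <- mk(disjoint, c("a", "b"))
  restr_df <- mk(restrictions, c("subject", "quantifier", "property", "filler",
                                 "provenance"))

  # referenced classes without their own owl:Class node still resolve
  referenced <- unique(c(cl_iri, isa_df$sub, isa_df$super, partof_df$part,
                         partof_df$whole, disjoint_df$a, disjoint_df$b,
                         restr_df$subject, restr_df$filler))
  classes_df <- data.frame(iri = referenced,
                           primary_name = pretty_name(referenced),
                           stringsAsFactors = FALSE)
  if (!is.null(lex_df)) {
    lab <- lex_df[lex_df$kind == "label", , drop = FALSE]
    first_lab <- lab$string[match(classes_df$iri, lab$iri)]
    classes_df$primary_name <- ifelse(is.na(first_lab),
                                      classes_df$primary_name, first_lab)
  }

  onto <- ontology(tag, classes_df, lex = lex_df, properties = prop_df,
                   isa = isa_df, partof = partof_df, disjoint = disjoint_df,
                   restrictions = restr_df,
                   cycle_policy = config$cycle_policy)
  if (!quiet)
    message(sprintf(
      "loaded %s: %d classes, %d lexicalizations, %d properties, %d isa, %d partof, %d disjoint, %d restrictions",
      tag, nrow(onto$classes), nrow(onto$lex), nrow(onto$properties),
      nrow(onto$isa), nrow(onto$partof), nrow(onto$disjoint),
      nrow(onto$restrictions)))
  onto
}

# Full namespace-resolved IRI of a child element (its RDF property).
child_property_iri <- function(child) {
  # xml_name() with a ns map gives "prefix:name"; resolve against the node's
  # in-scope namespace definitions instead for robustness
  nsdefs <- xml2::xml_ns(xml2::xml_root(child))
  qn <- strsplit(xml2::xml_name(child, nsdefs), ":", fixed = TRUE)[[1]]
  if (length(qn) == 2 && qn[1] %in% names(nsdefs))
    paste0(nsdefs[[qn[1]]], qn[2])
  else
    xml2::xml_name(child)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Write an ontology as OWL (RDF/XML)
#'
#' Emits the same OWL subset [load_ontology()] reads: class declarations with
#' labels and synonyms, named subclass axioms, asserted restriction
#' superclasses, PART-OF edges as existential restrictions on a `part_of`
#' property, and disjointness axioms.
#'
#' @param onto an `ontology`.
#' @param path output file path.
#' @param base_iri IRI prefix used for the generated `part_of` property when
#'   partonomy edges are present.
#' @return `path`, invisibly.
#' @export
write_owl <- function(onto, path,
                      base_iri = "http://example.org/onto#") {
  partof_iri <- paste0(base_iri, "part_of")
  out <- c(
    "<?xml version=\"1.0\"?>",
    "<rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
    "         xmlns:rdfs=\"http://www.w3.org/2000/01/rdf-schema#\"",
    "         xmlns:owl=\"http://www.w3.org/2002/07/owl#\"",
    "         xmlns:oboInOwl=\"http://www.geneontology.org/formats/oboInOwl#\">")
  for (p in onto$properties$iri) {
    out <- c(out, sprintf("  <owl:ObjectProperty rdf:about=\"%s\"/>",
                          xml_escape(p)))
  }
  if (nrow(onto$partof))
    out <- c(out, sprintf("  <owl:ObjectProperty rdf:about=\"%s\"/>",
                          xml_escape(partof_iri)))
  restr_block <- function(quant, prop, filler) {
    qtag <- if (quant == "existential") "owl:someValuesFrom" else "owl:allValuesFrom"
    c("    <rdfs:subClassOf>",
      "      <owl:Restriction>",
      sprintf("        <owl:onProperty rdf:resource=\"%s\"/>", xml_escape(prop)),
      sprintf("        <%s rdf:resource=\"%s\"/>", qtag, xml_escape(filler)),
      "      </owl:Restriction>",
      "    </rdfs:subClassOf>")
  }
  for (i in seq_len(nrow(onto$classes))) {
    iri <- onto$classes$iri[i]
    out <- c(out, sprintf("  <owl:Class rdf:about=\"%s\">", xml_escape(iri)))
    lx <- onto$lex[onto$lex$iri == iri, , drop = FALSE]
    for (k in seq_len(nrow(lx))) {
      if (lx$kind[k] == "synonym")
        out <- c(out, sprintf("    <oboInOwl:hasRelatedSynonym>%s</oboInOwl:hasRelatedSynonym>",
                              xml_escape(lx$string[k])))
      else
        out <- c(out, sprintf("    <rdfs:label>%s</rdfs:label>",
                              xml_escape(lx$string[k])))
    }
    sup <- onto$isa$super[onto$isa$sub == iri]
    for (s in sup)
      out <- c(out, sprintf("    <rdfs:subClassOf rdf:resource=\"%s\"/>",
                            xml_escape(s)))
    po <- onto$partof$whole[onto$partof$part == iri]
    for (w in po) out <- c(out, restr_block("existential", partof_iri, w))
    rs <- onto$restrictions[onto$restrictions$subject == iri &
                              onto$restrictions$provenance == "asserted", ,
                            drop = FALSE]
    for (k in seq_len(nrow(rs)))
      out <- c(out, restr_block(rs$quantifier[k], rs$property[k], rs$filler[k]))
    dj <- unique(c(onto$disjoint$b[onto$disjoint$a == iri],
                   onto$disjoint$a[onto$disjoint$b == iri]))
    # emit each unordered pair once, from its lexicographically first member
    for (d in dj[dj > iri])
      out <- c(out, sprintf("    <owl:disjointWith rdf:resource=\"%s\"/>",
                            xml_escape(d)))
    out <- c(out, "  </owl:Class>")
  }
  out <- c(out, "</rdf:RDF>")
  writeLines(out, path)
  invisible(path)
}
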