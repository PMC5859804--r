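# Shared helpers: random formal contexts and small hand-built ontologies.

random_context <- function(n_obj, n_attr, density = 0.4) {
  objs <- sprintf("o%02d", seq_len(n_obj))
  attrs <- sprintf("a%02d", seq_len(n_attr))
  inc <- matrix(stats::runif(n_obj * n_attr) < density, n_obj, n_attr)
  formal_context(objs, attrs, inc)
}

# brute-force concept set via power-set closure of object subsets
powerset_concepts <- function(ctx) {
  n <- length(ctx$objects)
  seen <- character(0)
  out <- list()
  for (mask in 0:(2^n - 1)) {
    sel <- ctx$objects[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    intent <- derive_attributes(ctx, sel)
    extent <- derive_objects(ctx, intent)
    key <- paste(sort(extent), collapse = "|")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- list(extent = sort(extent),
                                      intent = sort(intent))
    }
  }
  out[order(vapply(out, function(x) paste(x$extent, collapse = "|"),
                   character(1)))]
}

toy_iri <- function(tag, name) {
  paste0("http://fcamapr.example/", tag, "#",
         gsub("[^A-Za-z0-9]+", "_", name))
}

# bare-bones ontology builder over plain names
toy_onto <- function(tag, classes, isa = NULL, partof = NULL, disjoint = NULL,
                     properties = NULL, restrictions = NULL,
                     synonyms = list(), no_label = character(0)) {
  iri <- function(n) toy_iri(tag, n)
  lab <- setdiff(classes, no_label)
  lex <- data.frame(iri = iri(lab), string = lab, kind = "label",
                    stringsAsFactors = FALSE)
  for (cn in names(synonyms))
    lex <- rbind(lex, data.frame(iri = iri(cn), string = synonyms[[cn]],
                                 kind = "synonym", stringsAsFactors = FALSE))
  pair_df <- function(x, cols) {
    if (is.null(x)) return(NULL)
    m <- do.call(rbind, x)
    setNames(data.frame(iri(m[, 1]), iri(m[, 2]), stringsAsFactors = FALSE),
             cols)
  }
  restr <- if (is.null(restrictions)) NULL else {
    m <- do.call(rbind, restrictions)
    data.frame(subject = iri(m[, 1]), quantifier = m[, 2],
               property = iri(m[, 3]), filler = iri(m[, 4]),
               provenance = "asserted", stringsAsFactors = FALSE)
  }
  props <- if (is.null(properties)) NULL else
    data.frame(iri = iri(properties), name = properties,
               stringsAsFactors = FALSE)
  ontology(tag, data.frame(iri = iri(classes), primary_name = classes,
                           stringsAsFactors = FALSE),
           lex = lex, properties = props,
           isa = pair_df(isa, c("sub", "super")),
           partof = pair_df(partof, c("part", "whole")),
           disjoint = pair_df(disjoint, c("a", "b")),
           restrictions = restr)
}

toy_anchors <- function(tag1, tag2, pairs, types = NULL) {
  m <- do.call(rbind, pairs)
  out <- data.frame(class1 = toy_iri(tag1, m[, 1]),
                    class2 = toy_iri(tag2, m[, 2]),
                    type = if (is.null(types)) "TypeI" else types,
                    provenance = "test", stringsAsFactors = FALSE)
  out
}

pair_key_test <- function(d) paste(d$class1, d$class2)

concept_with_extent <- function(lattice, extent) {
  for (cpt in lattice$concepts)
    if (setequal(cpt$extent, extent)) return(cpt)
  NULL
}
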