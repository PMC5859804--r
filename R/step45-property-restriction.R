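#' Build the property-based formal context
#'
#' Objects are the object properties of both ontologies; attributes are
#' ordered pairs of distinct one-to-one class mappings
#' `<(C_Ai, C_Bi), (C_Aj, C_Bj)>`, kept only when realized by at least one
#' axiom. A property `g` is marked under such a pair when the axiom
#' `C_i ⊑ ∃g.C_j` or `C_i ⊑ ∀g.C_j` holds in its own ontology, either
#' asserted or inferred through the anonymous-ancestor closure.
#'
#' @param onto1,onto2 `ontology` objects.
#' @param mappings one-to-one class mapping data frame (`class1`, `class2`).
#' @return A `formal_context`, or `NULL` (with a message) when either
#'   ontology declares no object properties — the step is then skipped.
#' @export
build_property_context <- function(onto1, onto2, mappings) {
  if (!nrow(onto1$properties) || !nrow(onto2$properties)) {
    message("step 4 skipped: no object properties declared on one side")
    return(NULL)
  }
  objects <- c(paste0(onto1$tag, ":", onto1$properties$iri),
               paste0(onto2$tag, ":", onto2$properties$iri))
  # anonymous-ancestor closures per mapped class, computed once
  aa1 <- lapply(setNames(nm = unique(mappings$class1)), function(cl)
    anonymous_ancestors(onto1, cl))
  aa2 <- lapply(setNames(nm = unique(mappings$class2)), function(cl)
    anonymous_ancestors(onto2, cl))
  n <- nrow(mappings)
  attr_ids <- character(0); mark_sets <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    r1 <- aa1[[mappings$class1[i]]]
    r2 <- aa2[[mappings$class2[i]]]
    p1 <- unique(r1$property[r1$filler == mappings$class1[j]])
    p2 <- unique(r2$property[r2$filler == mappings$class2[j]])
    marked <- c(if (length(p1)) paste0(onto1$tag, ":", p1),
                if (length(p2)) paste0(onto2$tag, ":", p2))
    if (!length(marked)) next  # pair not realized by any axiom
    aid <- sprintf("<%s|%s>,<%s|%s>",
                   mappings$class1[i], mappings$class2[i],
                   mappings$class1[j], mappings$class2[j])
    attr_ids <- c(attr_ids, aid)
    mark_sets[[aid]] <- marked
  }
  if (!length(attr_ids)) {
    message("step 4: no realized mapping pair; property context is empty")
    return(NULL)
  }
  pairs <- do.call(rbind, lapply(attr_ids, function(a) cbind(mark_sets[[a]], a)))
  formal_context(objects, attr_ids, pairs)
}

#' Extract property mappings
#'
#' Every concept of the property lattice whose extent contains exactly two
#' properties, one from each ontology, yields a property mapping: the two
#' properties connect exactly the same pairs of class mappings.
#'
#' @param lattice GSH `lattice_view` of the property context.
#' @param tags length-2 character of source tags.
#' @return Data frame with columns `property1`, `property2`, `provenance`.
#' @export
extract_property_mappings <- function(lattice, tags) {
  src_of <- function(obj) sub(":.*$", "", obj)
  iri_of <- function(obj) sub("^[^:]*:", "", obj)
  rows <- list()
  for (i in seq_along(lattice$concepts)) {
    ext <- lattice$concepts[[i]]$extent
    if (length(ext) != 2) next
    s <- src_of(ext)
    if (!setequal(s, tags)) next
    rows[[length(rows) + 1L]] <- data.frame(
      property1 = iri_of(ext[s == tags[1]]),
      property2 = iri_of(ext[s == tags[2]]),
      provenance = sprintf("step4 property-lattice node %d", i),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(property1 = character(0), property2 = character(0),
               provenance = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$property1, out$property2, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate filler pairs from anonymous ancestors
#'
#' For each class mapping `(C_A, C_B)` and each property mapping `(g, h)`,
#' the fillers of `C_A`'s anonymous ancestors over `g` are crossed with the
#' fillers of `C_B`'s over `h`; quantifiers are ignored when pairing
#' (existential restrictions pair freely with universal ones) and recorded
#' in the provenance only. Pairs arising from several anchors are stored
#' once with merged provenance.
#'
#' @param onto1,onto2 `ontology` objects.
#' @param anchors one-to-one class mapping data frame.
#' @param prop_maps property mapping data frame
#'   (`property1`, `property2`).
#' @return Data frame with columns `filler1`, `filler2`, `provenance`.
#' @export
generate_filler_pairs <- function(onto1, onto2, anchors, prop_maps) {
  rows <- list()
  aa1 <- lapply(setNames(nm = unique(anchors$class1)), function(cl)
    anonymous_ancestors(onto1, cl))
  aa2 <- lapply(setNames(nm = unique(anchors$class2)), function(cl)
    anonymous_ancestors(onto2, cl))
  for (k in seq_len(nrow(anchors))) {
    r1 <- aa1[[anchors$class1[k]]]
    r2 <- aa2[[anchors$class2[k]]]
    if (!nrow(r1) || !nrow(r2)) next
    for (m in seq_len(nrow(prop_maps))) {
      f1 <- r1[r1$property == prop_maps$property1[m], , drop = FALSE]
      f2 <- r2[r2$property == prop_maps$property2[m], , drop = FALSE]
      if (!nrow(f1) || !nrow(f2)) next
      grid <- expand.grid(i = seq_len(nrow(f1)), j = seq_len(nrow(f2)))
      rows[[length(rows) + 1L]] <- data.frame(
        filler1 = f1$filler[grid$i], filler2 = f2$filler[grid$j],
        provenance = sprintf("anchor <%s|%s> propmap <%s|%s> quant %s/%s",
                             anchors$class1[k], anchors$class2[k],
                             prop_maps$property1[m], prop_maps$property2[m],
                             f1$quantifier[grid$i], f2$quantifier[grid$j]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(filler1 = character(0), filler2 = character(0),
                      provenance = character(0), stringsAsFactors = FALSE))
  }
  all <- do.call(rbind, rows)
  merged <- stats::aggregate(provenance ~ filler1 + filler2, data = all,
                             FUN = function(p) paste(sort(unique(p)),
                                                     collapse = " & "))
  merged <- merged[order(merged$filler1, merged$filler2, method = "radix"), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Build the restriction-based formal context
#'
#' Objects are the ontology-1 classes occurring in the filler-pair set,
#' attributes the ontology-2 classes, and the incidence is exactly
#' filler-pair membership.
#'
#' @param fp filler-pair data frame from [generate_filler_pairs()].
#' @return A `formal_context`, or `NULL` (with a message) when the pair set
#'   is empty — the step is then skipped.
#' @export
build_restriction_context <- function(fp) {
  if (!nrow(fp)) {
    message("step 5 skipped: empty filler-pair set")
    return(NULL)
  }
  formal_context(sort(unique(fp$filler1)), sort(unique(fp$filler2)),
                 fp[c("filler1", "filler2")])
}

#' Extract extended and complex mappings from the restriction lattice
#'
#' Concepts whose simplified extent and simplified intent each contain
#' exactly one class yield extended one-to-one mappings: the two classes
#' always occur together as fillers of mapped properties. Concepts with an
#' empty simplified intent and a non-empty simplified extent (or the dual)
#' yield complex-mapping candidates: the lone side is reported against the
#' concept's full dual set, with the semantic expression left to manual
#' review.
#'
#' @param lattice GSH `lattice_view` of the restriction context.
#' @return A list with `anchors` (type `"restriction"`) and `complex`
#'   (pattern `"restriction_complex"`, empty `expression`).
#' @export
extract_restriction_mappings <- function(lattice) {
  new_rows <- list(); complex_rows <- list()
  for (i in seq_along(lattice$concepts)) {
    cpt <- lattice$concepts[[i]]
    node <- sprintf("step5 restriction-lattice node %d", i)
    if (length(cpt$simplified_extent) == 1 &&
        length(cpt$simplified_intent) == 1) {
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        class1 = cpt$simplified_extent, class2 = cpt$simplified_intent,
        type = "restriction", provenance = node, stringsAsFactors = FALSE)
    } else if (length(cpt$simplified_intent) == 0 &&
               length(cpt$simplified_extent) > 0) {
      complex_rows[[length(complex_rows) + 1L]] <- data.frame(
        side1 = paste(cpt$simplified_extent, collapse = ";"),
        side2 = paste(cpt$intent, collapse = ";"),
        pattern = "restriction_complex", expression = "",
        review_required = TRUE, provenance = node, stringsAsFactors = FALSE)
    } else if (length(cpt$simplified_extent) == 0 &&
               length(cpt$simplified_intent) > 0) {
      complex_rows[[length(complex_rows) + 1L]] <- data.frame(
        side1 = paste(cpt$extent, collapse = ";"),
        side2 = paste(cpt$simplified_intent, collapse = ";"),
        pattern = "restriction_complex", expression = "",
        review_required = TRUE, provenance = node, stringsAsFactors = FALSE)
    }
  }
  anchors <- if (length(new_rows)) do.call(rbind, new_rows) else
    data.frame(class1 = character(0), class2 = character(0),
               type = character(0), provenance = character(0),
               stringsAsFactors = FALSE)
  cx <- if (length(complex_rows)) do.call(rbind, complex_rows) else
    data.frame(side1 = character(0), side2 = character(0),
               pattern = character(0), expression = character(0),
               review_required = logical(0), provenance = character(0),
               stringsAsFactors = FALSE)
  anchors <- anchors[order(anchors$class1, anchors$class2, method = "radix"), ,
                     drop = FALSE]
  cx <- cx[order(cx$side1, cx$side2, method = "radix"), , drop = FALSE]
  rownames(anchors) <- NULL; rownames(cx) <- NULL
  list(anchors = anchors, complex = cx)
}
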