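#' Build the positive relation-based formal context
#'
#' Like the relation-based context, but over the validated anchors and with
#' five positive relation labels — `(ISA)`, `(SUP)` (superclass-of), `(SIB)`,
#' `(PAT)` (part-of) and `(HPT)` (has-part) — and no disjointness.
#' `SUPERCLASS-OF` and `HAS-PART` are the inverses of the ISA and PART-OF
#' closures. Closures are strict: an anchor class does not mark its own
#' anchor's columns. Only realized columns are kept.
#'
#' @param onto1,onto2 `ontology` objects.
#' @param anchors validated anchor data frame.
#' @return A `formal_context`.
#' @export
build_posrel_context <- function(onto1, onto2, anchors) {
  if (!nrow(anchors)) stop("empty anchor set")
  q1 <- closure_queries(onto1); q2 <- closure_queries(onto2)
  objects <- c(paste0(onto1$tag, ":", onto1$classes$iri),
               paste0(onto2$tag, ":", onto2$classes$iri))
  mark_sets <- list(); attr_ids <- character(0)
  add_col <- function(attr, marked) {
    if (!length(marked)) return()
    attr_ids <<- c(attr_ids, attr)
    mark_sets[[attr]] <<- marked
  }
  tag_marks <- function(x, tag) if (length(x)) paste0(tag, ":", x) else character(0)
  haspart_of <- function(onto, q, cls) {
    onto$classes$iri[vapply(onto$classes$iri, function(x)
      cls %in% q$partof_wholes(x), logical(1))]
  }
  for (k in seq_len(nrow(anchors))) {
    c1 <- anchors$class1[k]; c2 <- anchors$class2[k]
    aid <- paste(c1, c2, sep = "|")
    add_col(rel_attr("ISA", aid),
            c(tag_marks(q1$isa_descendants(c1), onto1$tag),
              tag_marks(q2$isa_descendants(c2), onto2$tag)))
    add_col(rel_attr("SUP", aid),
            c(tag_marks(q1$isa_ancestors(c1), onto1$tag),
              tag_marks(q2$isa_ancestors(c2), onto2$tag)))
    add_col(rel_attr("SIB", aid),
            c(tag_marks(q1$siblings(c1), onto1$tag),
              tag_marks(q2$siblings(c2), onto2$tag)))
    add_col(rel_attr("PAT", aid),
            c(tag_marks(haspart_of(onto1, q1, c1), onto1$tag),
              tag_marks(haspart_of(onto2, q2, c2), onto2$tag)))
    add_col(rel_attr("HPT", aid),
            c(tag_marks(q1$partof_wholes(c1), onto1$tag),
              tag_marks(q2$partof_wholes(c2), onto2$tag)))
  }
  pairs <- do.call(rbind, lapply(attr_ids, function(a) cbind(mark_sets[[a]], a)))
  formal_context(objects, attr_ids, pairs)
}

#' Extract structural mappings from the positive relation lattice
#'
#' Concepts whose simplified extent contains classes from both ontologies
#' yield mappings: exactly one class from each side gives a new one-to-one
#' structural mapping (pairs already present among the input anchors are
#' dropped as duplicates); one class on one side and several on the other
#' give a one-to-group complex mapping; several on both sides give a
#' group-to-group complex mapping. Group sides are reported as disjunction
#' expressions and flagged for manual review; complex mappings are never fed
#' into later steps.
#'
#' @param lattice GSH `lattice_view` of the positive relation context.
#' @param anchors the validated anchors (for duplicate suppression).
#' @param tags length-2 character of source tags.
#' @param name_of optional function mapping `"<TAG>:<iri>"` to a display
#'   name for expression hints (default: the IRI local name).
#' @return A list with `anchors` (new one-to-one mappings, type
#'   `"structural"`) and `complex` (data frame with `side1`, `side2`,
#'   `pattern`, `expression`, `review_required`; sides are `;`-separated IRI
#'   lists).
#' @export
extract_structural_mappings <- function(lattice, anchors, tags,
                                        name_of = NULL) {
  if (is.null(name_of))
    name_of <- function(x) pretty_name(sub("^[^:]*:", "", x))
  src_of <- function(obj) sub(":.*$", "", obj)
  iri_of <- function(obj) sub("^[^:]*:", "", obj)
  known <- anchor_id(anchors)
  new_rows <- list(); complex_rows <- list()
  for (i in seq_along(lattice$concepts)) {
    cpt <- lattice$concepts[[i]]
    if (!length(cpt$intent)) next  # degenerate top: classes sharing nothing
    kex <- cpt$simplified_extent
    s1 <- kex[src_of(kex) == tags[1]]
    s2 <- kex[src_of(kex) == tags[2]]
    if (!length(s1) || !length(s2)) next
    node <- sprintf("step3 posrel-lattice node %d", i)
    if (length(s1) == 1 && length(s2) == 1) {
      aid <- paste(iri_of(s1), iri_of(s2), sep = "|")
      if (aid %in% known) next
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        class1 = iri_of(s1), class2 = iri_of(s2), type = "structural",
        provenance = node, stringsAsFactors = FALSE)
    } else {
      pattern <- if (length(s1) == 1 || length(s2) == 1) "one_to_group"
                 else "group_to_group"
      expr_side <- function(objs) {
        if (length(objs) == 1) name_of(objs)
        else paste0("(", paste(vapply(objs, name_of, character(1)),
                               collapse = " ⊔ "), ")")
      }
      complex_rows[[length(complex_rows) + 1L]] <- data.frame(
        side1 = paste(iri_of(s1), collapse = ";"),
        side2 = paste(iri_of(s2), collapse = ";"),
        pattern = pattern,
        expression = paste(expr_side(s1), "<->", expr_side(s2)),
        review_required = TRUE, provenance = node,
        stringsAsFactors = FALSE)
    }
  }
  empty_anchor <- data.frame(class1 = character(0), class2 = character(0),
                             type = character(0), provenance = character(0),
                             stringsAsFactors = FALSE)
  empty_complex <- data.frame(side1 = character(0), side2 = character(0),
                              pattern = character(0), expression = character(0),
                              review_required = logical(0),
                              provenance = character(0),
                              stringsAsFactors = FALSE)
  new_a <- if (length(new_rows)) do.call(rbind, new_rows) else empty_anchor
  cx <- if (length(complex_rows)) do.call(rbind, complex_rows) else empty_complex
  new_a <- unique(new_a)
  new_a <- new_a[order(new_a$class1, new_a$class2, method = "radix"), ,
                 drop = FALSE]
  cx <- unique(cx)
  cx <- cx[order(cx$side1, cx$side2, method = "radix"), , drop = FALSE]
  rownames(new_a) <- NULL; rownames(cx) <- NULL
  list(anchors = new_a, complex = cx)
}
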