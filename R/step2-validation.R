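#' Anchor and class identifiers used by the relation contexts
#'
#' Classes from the two ontologies become context objects `"<TAG>:<iri>"`;
#' relation attributes are `"(<LABEL>)<anchor id>"` where the anchor id is
#' `"<iri1>|<iri2>"`.
#'
#' @name relation_ids
#' @keywords internal
NULL

anchor_id <- function(anchors) paste(anchors$class1, anchors$class2, sep = "|")

rel_attr <- function(label, aid) sprintf("(%s)%s", label, aid)

parse_rel_attr <- function(attr) {
  m <- regmatches(attr, regexec("^\\(([A-Z-]+)\\)(.*)$", attr))[[1]]
  list(label = m[2], aid = m[3])
}

#' Build the relation-based formal context
#'
#' Objects are all classes of both ontologies; attributes are the lexical
#' anchors prefixed with a relationship label: `(ISA)`, `(SIB)`, `(PAT)` for
#' taxonomic, sibling and partonomic relations, and the mixed conflict labels
#' `(I-D)` (ISA on the ontology-1 side, DISJOINT on the ontology-2 side) and
#' `(D-I)` (the reverse). A class is marked under an attribute when it stands
#' in the labelled relation — via the inferred closures — to the same-side
#' class of the attribute's anchor. ISA marks are strict (a class does not
#' ISA-relate to itself). Only realized (non-empty) attribute columns are
#' kept; the printed cross-tables of such contexts are fragments of exactly
#' this construction.
#'
#' @param onto1,onto2 `ontology` objects.
#' @param anchors anchor data frame (`class1` from `onto1`, `class2` from
#'   `onto2`).
#' @param drop_empty drop attribute columns with no marks (default `TRUE`).
#' @return A `formal_context`.
#' @export
build_relation_context <- function(onto1, onto2, anchors, drop_empty = TRUE) {
  if (!nrow(anchors)) stop("empty anchor set")
  q1 <- closure_queries(onto1); q2 <- closure_queries(onto2)
  obj1 <- paste0(onto1$tag, ":", onto1$classes$iri)
  obj2 <- paste0(onto2$tag, ":", onto2$classes$iri)
  objects <- c(obj1, obj2)

  mark_sets <- list(); attr_ids <- character(0)
  add_col <- function(attr, marked) {
    if (drop_empty && !length(marked)) return()
    attr_ids <<- c(attr_ids, attr)
    mark_sets[[attr]] <<- marked
  }
  tag_marks <- function(tagged, side) {
    if (!length(tagged)) return(character(0))
    paste0(side, ":", tagged)
  }

  for (k in seq_len(nrow(anchors))) {
    c1 <- anchors$class1[k]; c2 <- anchors$class2[k]
    aid <- paste(c1, c2, sep = "|")
    isa1 <- q1$isa_descendants(c1); isa2 <- q2$isa_descendants(c2)
    add_col(rel_attr("ISA", aid),
            c(tag_marks(isa1, onto1$tag), tag_marks(isa2, onto2$tag)))
    sib1 <- q1$siblings(c1); sib2 <- q2$siblings(c2)
    add_col(rel_attr("SIB", aid),
            c(tag_marks(sib1, onto1$tag), tag_marks(sib2, onto2$tag)))
    pat1 <- onto1$classes$iri[vapply(onto1$classes$iri, function(x)
      c1 %in% q1$partof_wholes(x), logical(1))]
    pat2 <- onto2$classes$iri[vapply(onto2$classes$iri, function(x)
      c2 %in% q2$partof_wholes(x), logical(1))]
    add_col(rel_attr("PAT", aid),
            c(tag_marks(pat1, onto1$tag), tag_marks(pat2, onto2$tag)))
    dis1 <- onto1$classes$iri[vapply(onto1$classes$iri, function(x)
      c1 %in% q1$disjoint_classes(x), logical(1))]
    dis2 <- onto2$classes$iri[vapply(onto2$classes$iri, function(x)
      c2 %in% q2$disjoint_classes(x), logical(1))]
    # (I-D): ISA on the O1 side, DISJOINT on the O2 side; a column is a
    # conflict witness only if both sides are realized
    if (length(isa1) && length(dis2))
      add_col(rel_attr("I-D", aid),
              c(tag_marks(isa1, onto1$tag), tag_marks(dis2, onto2$tag)))
    if (length(dis1) && length(isa2))
      add_col(rel_attr("D-I", aid),
              c(tag_marks(dis1, onto1$tag), tag_marks(isa2, onto2$tag)))
  }
  pairs <- do.call(rbind, lapply(attr_ids, function(a) {
    if (!length(mark_sets[[a]])) return(NULL)
    cbind(mark_sets[[a]], a)
  }))
  formal_context(objects, attr_ids, pairs)
}

#' Compute positive and negative structural evidence
#'
#' For each anchor `a = (c1, c2)`, the attributes shared by both its classes
#' in the relation-based context are scanned: `a` becomes positive evidence
#' for the attribute's anchor `b` when the label is `(ISA)`, `(SIB)` or
#' `(PAT)` (`a` joins `P(b)`), and negative evidence when the label is
#' `(I-D)` or `(D-I)` (`a` joins `N(b)`). The support and conflict degree of
#' an anchor are the cardinalities of its evidence sets.
#'
#' @param context relation-based `formal_context` built over `anchors`.
#' @param anchors anchor data frame.
#' @param tags length-2 character of source tags.
#' @return A list with named elements `P`, `N` (lists of anchor-id character
#'   vectors keyed by anchor id), and `support`, `conflict` (named integer
#'   vectors).
#' @export
compute_evidence <- function(context, anchors, tags) {
  aids <- anchor_id(anchors)
  P <- setNames(vector("list", length(aids)), aids)
  N <- setNames(vector("list", length(aids)), aids)
  for (i in seq_along(aids)) P[[i]] <- character(0)
  for (i in seq_along(aids)) N[[i]] <- character(0)
  pos_labels <- c("ISA", "SIB", "PAT")
  for (k in seq_len(nrow(anchors))) {
    o1 <- paste0(tags[1], ":", anchors$class1[k])
    o2 <- paste0(tags[2], ":", anchors$class2[k])
    missing <- setdiff(c(o1, o2), context$objects)
    if (length(missing))
      stop("anchor class missing from relation context: ",
           paste(missing, collapse = ", "))
    shared <- derive_attributes(context, c(o1, o2))
    for (attr in shared) {
      pa <- parse_rel_attr(attr)
      if (!(pa$aid %in% aids)) next
      if (pa$label %in% pos_labels) {
        P[[pa$aid]] <- union(P[[pa$aid]], aids[k])
      } else {
        N[[pa$aid]] <- union(N[[pa$aid]], aids[k])
      }
    }
  }
  list(P = lapply(P, sort), N = lapply(N, sort),
       support = vapply(P, length, integer(1)),
       conflict = vapply(N, length, integer(1)))
}

#' Repair anchor conflicts greedily
#'
#' While any negative-evidence set is non-empty: select the anchor `a` with
#' the smallest conflict degree (ties: larger support degree, then
#' lexicographic id); for each `b` in `N(a)`, eliminate `b` if its conflict
#' degree exceeds `a`'s, otherwise eliminate whichever of the two has the
#' smaller support degree (tie: the Type II one; double tie: the
#' lexicographically greater id). Evidence is recomputed over the survivors
#' after every elimination, so degrees always reflect the current anchor
#' set; the loop terminates because each iteration removes at least one
#' anchor.
#'
#' @param onto1,onto2 `ontology` objects.
#' @param anchors anchor data frame.
#' @param log_path optional path for the repair log (one line per
#'   elimination).
#' @return The surviving anchor data frame (attribute `repair_log` carries
#'   the log lines).
#' @export
repair_conflicts <- function(onto1, onto2, anchors, log_path = NULL) {
  tags <- c(onto1$tag, onto2$tag)
  surv <- anchors
  log <- character(0)
  type_of <- function(aid) surv$type[match(aid, anchor_id(surv))]
  repeat {
    if (!nrow(surv)) break
    ctx <- build_relation_context(onto1, onto2, surv)
    ev <- compute_evidence(ctx, surv, tags)
    conflicted <- names(ev$N)[vapply(ev$N, length, integer(1)) > 0]
    if (!length(conflicted)) break
    # pick a: smallest conflict degree, ties larger support, then id
    ord <- order(ev$conflict[conflicted], -ev$support[conflicted],
                 conflicted, method = "radix")
    a <- conflicted[ord[1]]
    eliminated <- NULL
    for (b in ev$N[[a]]) {
      if (ev$conflict[b] > ev$conflict[a]) {
        eliminated <- b; reason <- "greater conflict degree"
      } else if (ev$support[a] < ev$support[b]) {
        eliminated <- a; reason <- "smaller support degree"
      } else if (ev$support[b] < ev$support[a]) {
        eliminated <- b; reason <- "smaller support degree"
      } else if (type_of(a) == "TypeII" && type_of(b) != "TypeII") {
        eliminated <- a; reason <- "support tie, TypeII eliminated"
      } else if (type_of(b) == "TypeII" && type_of(a) != "TypeII") {
        eliminated <- b; reason <- "support tie, TypeII eliminated"
      } else {
        eliminated <- max(a, b); reason <- "full tie, lexicographic"
      }
      log <- c(log, sprintf(
        "eliminate %s (%s; conflict %d vs %d, support %d vs %d, vs %s)",
        eliminated, reason, ev$conflict[a], ev$conflict[b],
        ev$support[a], ev$support[b], setdiff(c(a, b), eliminated)))
      surv <- surv[anchor_id(surv) != eliminated, , drop = FALSE]
      break  # evidence must be recomputed before the next elimination
    }
  }
  if (!is.null(log_path)) writeLines(log, log_path)
  attr(surv, "repair_log") <- log
  rownames(surv) <- NULL
  surv
}

#' Screen anchors on structural support
#'
#' After conflict repair, Type II anchors whose support degree is zero (no
#' positive structural evidence) are eliminated; Type I anchors are retained
#' regardless, their lexical certainty standing on its own.
#'
#' @param onto1,onto2 `ontology` objects.
#' @param anchors repaired anchor data frame.
#' @return The screened anchor data frame.
#' @export
screen_anchors <- function(onto1, onto2, anchors) {
  if (!nrow(anchors)) return(anchors)
  ctx <- build_relation_context(onto1, onto2, anchors)
  ev <- compute_evidence(ctx, anchors, c(onto1$tag, onto2$tag))
  keep <- anchors$type != "TypeII" | ev$support[anchor_id(anchors)] > 0
  out <- anchors[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
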