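#' Ontology objects
#'
#' An `ontology` holds the views of an OWL ontology the matching steps
#' consume: named classes with their lexicalizations (labels and synonyms),
#' object properties, ISA and PART-OF edges, disjointness pairs, and
#' restriction superclass axioms (quantified property restrictions, the
#' "anonymous ancestors" once closed).
#'
#' @param tag short source tag (e.g. `"MA"`, `"NCI"`, `"O1"`).
#' @param classes data frame with columns `iri`, `primary_name`.
#' @param lex data frame with columns `iri`, `string`, `kind`
#'   (`"name"`, `"label"` or `"synonym"`).
#' @param properties data frame with columns `iri`, `name`.
#' @param isa data frame with columns `sub`, `super` (named-class subclass
#'   axioms).
#' @param partof data frame with columns `part`, `whole`.
#' @param disjoint data frame with columns `a`, `b` (unordered pairs).
#' @param restrictions data frame with columns `subject`, `quantifier`
#'   (`"existential"` / `"universal"`), `property`, `filler`, `provenance`.
#' @param cycle_policy `"fatal"` (reject ISA cycles) or `"collapse"`.
#' @return An object of class `ontology`.
#' @export
ontology <- function(tag, classes, lex = NULL, properties = NULL, isa = NULL,
                     partof = NULL, disjoint = NULL, restrictions = NULL,
                     cycle_policy = "fatal") {
  df <- function(x, cols) {
    if (is.null(x) || !nrow(as.data.frame(x))) {
      out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    } else {
      out <- as.data.frame(x, stringsAsFactors = FALSE)
      stopifnot(all(cols %in% names(out)))
      out <- out[cols]
    }
    out
  }
  classes <- df(classes, c("iri", "primary_name"))
  if (anyDuplicated(classes$iri)) stop("duplicate class IRIs")
  if (any(!nzchar(classes$primary_name))) stop("empty primary name")
  lex <- unique(df(lex, c("iri", "string", "kind")))
  properties <- df(properties, c("iri", "name"))
  if (anyDuplicated(properties$iri)) stop("duplicate property IRIs")
  isa <- unique(df(isa, c("sub", "super")))
  partof <- unique(df(partof, c("part", "whole")))
  disjoint <- df(disjoint, c("a", "b"))
  if (nrow(disjoint)) {  # store unordered, deduplicated
    lo <- pmin(disjoint$a, disjoint$b); hi <- pmax(disjoint$a, disjoint$b)
    disjoint <- unique(data.frame(a = lo, b = hi, stringsAsFactors = FALSE))
  }
  restrictions <- unique(df(restrictions,
                            c("subject", "quantifier", "property", "filler",
                              "provenance")))
  known <- classes$iri
  check_in <- function(v, what) {
    bad <- setdiff(v, known)
    if (length(bad)) stop(what, " references unknown class: ",
                          paste(bad, collapse = ", "))
  }
  check_in(c(isa$sub, isa$super), "isa edge")
  check_in(c(partof$part, partof$whole), "partof edge")
  check_in(c(disjoint$a, disjoint$b), "disjointness")
  check_in(c(restrictions$subject, restrictions$filler), "restriction")
  bad_p <- setdiff(restrictions$property, properties$iri)
  if (length(bad_p)) stop("restriction references unknown property: ",
                          paste(bad_p, collapse = ", "))

  onto <- structure(list(tag = tag, classes = classes, lex = lex,
                         properties = properties, isa = isa, partof = partof,
                         disjoint = disjoint, restrictions = restrictions),
                    class = "ontology")
  cyc <- isa_cycles(onto)
  if (length(cyc)) {
    if (identical(cycle_policy, "collapse")) {
      onto <- collapse_isa_cycles(onto, cyc)
    } else {
      stop("ISA cycle detected: ",
           paste(vapply(cyc, paste, character(1), collapse = " -> "),
                 collapse = "; "))
    }
  }
  onto
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf(paste0("<ontology %s> %d classes, %d lexicalizations, ",
                     "%d properties, %d isa, %d partof, %d disjoint, ",
                     "%d restrictions\n"),
              x$tag, nrow(x$classes), nrow(x$lex), nrow(x$properties),
              nrow(x$isa), nrow(x$partof), nrow(x$disjoint),
              nrow(x$restrictions)))
  invisible(x)
}

# Strongly connected components of the ISA graph with size > 1, via pairwise
# reachability (ontology fixtures are small; clarity over asymptotics).
isa_cycles <- function(onto) {
  edges <- onto$isa
  if (!nrow(edges)) return(list())
  reach <- reachability(edges$sub, edges$super)
  nodes <- names(reach)
  seen <- character(0); sccs <- list()
  for (v in nodes) {
    if (v %in% seen) next
    comp <- v
    for (w in reach[[v]]) {
      if (w != v && v %in% reach_of(reach, w)) comp <- c(comp, w)
    }
    if (length(comp) > 1) {
      sccs[[length(sccs) + 1L]] <- sort(comp)
      seen <- c(seen, comp)
    }
  }
  sccs
}

# Forward reachability sets (strict: a node is not its own ancestor unless on
# a cycle) for an edge list, as a named list keyed by source node.
reachability <- function(from, to) {
  nodes <- sort(unique(c(from, to)))
  adj <- split(to, factor(from, levels = nodes))
  out <- setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) {
    frontier <- adj[[v]]
    seen <- character(0)
    while (length(frontier)) {
      new <- setdiff(frontier, seen)
      seen <- c(seen, new)
      frontier <- unique(unlist(adj[new], use.names = FALSE))
    }
    out[[v]] <- sort(seen)
  }
  out
}

reach_of <- function(reach, v) {
  r <- reach[[v]]
  if (is.null(r)) character(0) else r
}

# Collapse each SCC onto its lexicographically first member.
collapse_isa_cycles <- function(onto, sccs) {
  remap <- setNames(onto$classes$iri, onto$classes$iri)
  for (comp in sccs) remap[comp] <- comp[1]
  rm_dup <- function(d, cols) {
    for (cl in cols) d[[cl]] <- unname(remap[d[[cl]]])
    unique(d)
  }
  onto$classes <- onto$classes[onto$classes$iri %in% unique(remap), , drop = FALSE]
  onto$lex <- rm_dup(onto$lex, "iri")
  onto$isa <- rm_dup(onto$isa, c("sub", "super"))
  onto$isa <- onto$isa[onto$isa$sub != onto$isa$super, , drop = FALSE]
  onto$partof <- rm_dup(onto$partof, c("part", "whole"))
  onto$disjoint <- rm_dup(onto$disjoint, c("a", "b"))
  onto$restrictions <- rm_dup(onto$restrictions, c("subject", "filler"))
  onto
}

#' Serialize an ontology to the line-oriented dump format
#'
#' One axiom per line; reloading with [read_ontology_dump()] reproduces an
#' identical structure. Intended for fixtures and debugging.
#'
#' @param onto an `ontology`.
#' @param path file path.
#' @return `path`, invisibly; `read_ontology_dump()` returns an `ontology`.
#' @export
write_ontology_dump <- function(onto, path) {
  esc <- function(x) gsub("\t", " ", x, fixed = TRUE)
  lines <- c(paste0("tag\t", onto$tag),
             sprintf("class\t%s\t%s", esc(onto$classes$iri),
                     esc(onto$classes$primary_name)),
             sprintf("lex\t%s\t%s\t%s", esc(onto$lex$iri), esc(onto$lex$string),
                     onto$lex$kind),
             sprintf("property\t%s\t%s", esc(onto$properties$iri),
                     esc(onto$properties$name)),
             sprintf("isa\t%s\t%s", onto$isa$sub, onto$isa$super),
             sprintf("partof\t%s\t%s", onto$partof$part, onto$partof$whole),
             sprintf("disjoint\t%s\t%s", onto$disjoint$a, onto$disjoint$b),
             sprintf("restriction\t%s\t%s\t%s\t%s\t%s",
                     onto$restrictions$subject, onto$restrictions$quantifier,
                     onto$restrictions$property, onto$restrictions$filler,
                     onto$restrictions$provenance))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ontology_dump
#' @export
read_ontology_dump <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  grab <- function(kind, n) {
    rows <- Filter(function(p) p[1] == kind, parts)
    if (!length(rows)) return(NULL)
    do.call(rbind, lapply(rows, function(p) p[2:(n + 1)]))
  }
  tag <- grab("tag", 1)[1, 1]
  cl <- grab("class", 2)
  lx <- grab("lex", 3)
  pr <- grab("property", 2)
  is <- grab("isa", 2)
  po <- grab("partof", 2)
  dj <- grab("disjoint", 2)
  rs <- grab("restriction", 5)
  mk <- function(m, cols) if (is.null(m)) NULL else
    setNames(as.data.frame(m, stringsAsFactors = FALSE), cols)
  ontology(tag,
           classes = mk(cl, c("iri", "primary_name")),
           lex = mk(lx, c("iri", "string", "kind")),
           properties = mk(pr, c("iri", "name")),
           isa = mk(is, c("sub", "super")),
           partof = mk(po, c("part", "whole")),
           disjoint = mk(dj, c("a", "b")),
           restrictions = mk(rs, c("subject", "quantifier", "property",
                                   "filler", "provenance")))
}

#' Lexicalizations of an ontology's classes
#'
#' Returns one row per (class, string): the class's labels and synonyms, or
#' its primary name when it has neither. These strings are the objects of the
#' token-based context.
#'
#' @param onto an `ontology`.
#' @return Data frame with columns `iri`, `string`, `kind`, `source`.
#' @export
lexicalizations <- function(onto) {
  out <- onto$lex
  missing <- setdiff(onto$classes$iri, out$iri)
  if (length(missing)) {
    nm <- onto$classes$primary_name[match(missing, onto$classes$iri)]
    out <- rbind(out, data.frame(iri = missing, string = nm, kind = "name",
                                 stringsAsFactors = FALSE))
  }
  out <- unique(out)
  out$source <- onto$tag
  out[order(out$iri, out$kind, out$string, method = "radix"), , drop = FALSE]
}
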