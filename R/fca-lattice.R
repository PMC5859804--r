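#' Formal concepts and lattice views
#'
#' A formal concept of a context is a pair (A, B) with A = B' and B = A'
#' (extent and intent closed under the derivation operators). The simplified
#' extent of (A, B) collects the objects introduced at that concept (those g
#' whose object concept is (A, B)); the simplified intent dually collects the
#' attributes m whose attribute concept is (A, B). Simplified labels are the
#' basis of all extraction rules in the matching steps.
#'
#' @name formal_concept
NULL

canonical_extent_key <- function(extent) paste(sort(extent), collapse = "\x1f")

# Build one concept record from a closed extent.
make_concept <- function(context, extent) {
  intent <- derive_attributes(context, extent)
  inc <- context$incidence
  # gamma(g) == (A,B)  <=>  g'' == A  <=>  |g'| attributes pick out exactly A
  kex <- extent[vapply(extent, function(g) {
    attrs <- context$attributes[inc[g, ]]
    length(derive_objects(context, attrs)) == length(extent)
  }, logical(1))]
  # mu(m) == (A,B)  <=>  m' == A
  kin <- intent[vapply(intent, function(m) {
    sum(inc[, m]) == length(extent)
  }, logical(1))]
  structure(list(extent = extent, intent = intent,
                 simplified_extent = kex, simplified_intent = kin),
            class = "formal_concept")
}

#' @export
print.formal_concept <- function(x, ...) {
  cat(sprintf("<concept> extent {%s} intent {%s}\n",
              paste(x$extent, collapse = ", "),
              paste(x$intent, collapse = ", ")))
  invisible(x)
}

lattice_view <- function(context, extents, kind) {
  # deterministic node order: by extent size, then canonical extent string
  keys <- vapply(extents, canonical_extent_key, character(1))
  sizes <- lengths(extents)
  ord <- order(sizes, keys, method = "radix")
  extents <- extents[ord]
  concepts <- lapply(extents, function(e) make_concept(context, e))
  n <- length(concepts)
  sub <- integer(0); sup <- integer(0)
  if (n > 1) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && length(concepts[[i]]$extent) <= length(concepts[[j]]$extent) &&
          all(concepts[[i]]$extent %in% concepts[[j]]$extent) &&
          !setequal(concepts[[i]]$extent, concepts[[j]]$extent)) {
        sub <- c(sub, i); sup <- c(sup, j)
      }
    }
  }
  structure(list(concepts = concepts,
                 order = cbind(sub = sub, sup = sup),
                 kind = kind),
            class = "lattice_view")
}

#' @export
print.lattice_view <- function(x, ...) {
  cat(sprintf("<lattice_view kind=%s> %d concepts, %d order pairs\n",
              x$kind, length(x$concepts), nrow(x$order)))
  invisible(x)
}

#' Enumerate all formal concepts (brute-force oracle)
#'
#' Computes the complete concept lattice by closing every attribute-column
#' intersection. Exponential in the worst case, so guarded to small contexts;
#' it serves as the correctness oracle for [build_gsh()].
#'
#' @param context a `formal_context` with at most `max_size` objects and
#'   attributes.
#' @param max_size size guard (default 20).
#' @return A `lattice_view` with `kind = "full"` containing every concept.
#' @export
enumerate_concepts <- function(context, max_size = 20) {
  if (length(context$objects) > max_size || length(context$attributes) > max_size)
    stop("context too large for brute-force enumeration (oracle use only)")
  # all extents are intersections of attribute extents, seeded with G
  extents <- list(context$objects)
  keys <- canonical_extent_key(context$objects)
  for (m in context$attributes) {
    mext <- context$objects[context$incidence[, m]]
    for (e in extents) {
      cand <- intersect(e, mext)
      k <- canonical_extent_key(cand)
      if (!(k %in% keys)) {
        extents[[length(extents) + 1L]] <- cand
        keys <- c(keys, k)
      }
    }
  }
  # the bottom concept (intent = M) arises as the empty intersection already;
  # ensure B' closure holds for the top: G is closed by construction of intents
  lattice_view(context, extents, kind = "full")
}

#' Build the Galois sub-hierarchy (AOC poset)
#'
#' The Galois sub-hierarchy restricts the concept lattice to the object
#' concepts (the smallest concept containing each object) and attribute
#' concepts (the greatest concept whose intent contains each attribute),
#' with the induced order. It is polynomial-sized yet preserves all the
#' simplified labels the extraction rules need.
#'
#' @param context a `formal_context`.
#' @return A `lattice_view` with `kind = "gsh"`.
#' @export
build_gsh <- function(context) {
  extents <- list()
  keys <- character(0)
  add <- function(e) {
    k <- canonical_extent_key(e)
    if (!(k %in% keys)) {
      extents[[length(extents) + 1L]] <<- e
      keys <<- c(keys, k)
    }
  }
  for (g in context$objects) {
    attrs <- context$attributes[context$incidence[g, ]]
    add(derive_objects(context, attrs))        # extent of gamma(g) = g''
  }
  for (m in context$attributes) {
    add(context$objects[context$incidence[, m]])  # extent of mu(m) = m'
  }
  lattice_view(context, extents, kind = "gsh")
}

#' Serialize a lattice view as text
#'
#' One line per concept (extent, intent, simplified labels) plus the order
#' pairs; identical contexts always produce identical dumps.
#'
#' @param lattice a `lattice_view`.
#' @return A character vector of lines.
#' @export
format_lattice <- function(lattice) {
  fmt_set <- function(s) paste(s, collapse = ", ")
  lines <- vapply(seq_along(lattice$concepts), function(i) {
    cpt <- lattice$concepts[[i]]
    sprintf("#%d extent={%s} intent={%s} Kex={%s} Kin={%s}",
            i, fmt_set(cpt$extent), fmt_set(cpt$intent),
            fmt_set(cpt$simplified_extent), fmt_set(cpt$simplified_intent))
  }, character(1))
  if (nrow(lattice$order)) {
    ord <- apply(lattice$order, 1, function(p) sprintf("%d <= %d", p[1], p[2]))
    lines <- c(lines, paste("order:", paste(ord, collapse = "; ")))
  }
  lines
}
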