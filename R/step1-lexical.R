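#' Build the token-based formal context
#'
#' Objects are the lexicalizations (labels, synonyms, or fallback names) of
#' both ontologies, identified as `"<TAG>:<string>"`; the same string used by
#' several classes of one ontology is a single object with several origin
#' classes. Attributes are the canonical tokens of those strings; the
#' incidence holds where the normalized string contains the token. Strings
#' normalizing to the empty token set are dropped with a warning.
#'
#' @param onto1,onto2 `ontology` objects (the two sources).
#' @param lexicon a [token_lexicon()].
#' @return A list with elements `context` (a `formal_context`) and `index`
#'   (data frame mapping object ids to `raw`, `source`, and origin `iri`s;
#'   one row per (object, origin class)).
#' @export
build_token_context <- function(onto1, onto2, lexicon = token_lexicon()) {
  lex <- rbind(lexicalizations(onto1), lexicalizations(onto2))
  if (!nrow(lex)) stop("no lexicalizations in either ontology")
  lex$object <- paste0(lex$source, ":", lex$string)
  toksets <- lapply(unique(lex$object), function(o) {
    normalize(lex$string[match(o, lex$object)], lexicon)
  })
  names(toksets) <- unique(lex$object)
  empty <- names(toksets)[lengths(toksets) == 0]
  if (length(empty)) {
    warning("dropping ", length(empty),
            " string(s) normalizing to the empty token set: ",
            paste(empty, collapse = ", "))
    toksets <- toksets[lengths(toksets) > 0]
  }
  if (!length(toksets)) stop("no lexicalization survives normalization")
  objects <- names(toksets)
  attributes <- sort(unique(unlist(toksets, use.names = FALSE)))
  pairs <- do.call(rbind, lapply(objects, function(o) {
    cbind(o, toksets[[o]])
  }))
  ctx <- formal_context(objects, attributes, pairs)
  index <- unique(lex[lex$object %in% objects,
                      c("object", "raw" = "string", "source", "iri", "kind")])
  names(index)[names(index) == "string"] <- "raw"
  rownames(index) <- NULL
  list(context = ctx, index = index)
}

# Origin classes (per source) of a set of token-context objects.
class_origins <- function(object_ids, index) {
  rows <- index[index$object %in% object_ids, , drop = FALSE]
  unique(rows[c("source", "iri")])
}

#' Extract lexical anchors from the token lattice
#'
#' Implements the two anchor rules over the Galois sub-hierarchy of the
#' token-based context:
#'
#' * **Type I** (exact match): the concept's simplified extent contains
#'   exactly two strings, one from each ontology — the strings are composed
#'   of the same or synonymous tokens, and their origin classes are matched.
#' * **Type II** (unique partial match): the concept's class-origin extent
#'   (origin classes of all strings in the full extent) contains exactly two
#'   classes, one from each ontology, and the simplified extent holds strings
#'   from at most one ontology (including none) — the shared tokens exist
#'   solely in these two classes.
#'
#' Duplicate pairs are deduplicated with Type I precedence; output order is
#' deterministic.
#'
#' @param lattice `lattice_view` (GSH) of the token context.
#' @param index the lexicalization index from [build_token_context()].
#' @param tags length-2 character: the source tags of ontology 1 and 2.
#' @return Anchor data frame with columns `class1`, `class2`, `type`,
#'   `provenance`.
#' @export
extract_anchors <- function(lattice, index, tags) {
  stopifnot(length(tags) == 2)
  src_of <- function(obj) sub(":.*$", "", obj)
  anchors <- list()
  add <- function(c1, c2, type, prov) {
    anchors[[length(anchors) + 1L]] <<- data.frame(
      class1 = c1, class2 = c2, type = type, provenance = prov,
      stringsAsFactors = FALSE)
  }
  for (i in seq_along(lattice$concepts)) {
    cpt <- lattice$concepts[[i]]
    kex <- cpt$simplified_extent
    kex_src <- unique(src_of(kex))
    node <- sprintf("token-lattice node %d", i)
    # Type I: exactly two strings in K_ex, one per ontology
    if (length(kex) == 2 && setequal(kex_src, tags)) {
      o1 <- kex[src_of(kex) == tags[1]]
      o2 <- kex[src_of(kex) == tags[2]]
      org1 <- class_origins(o1, index)$iri
      org2 <- class_origins(o2, index)$iri
      for (c1 in org1) for (c2 in org2)
        add(c1, c2, "TypeI", paste0("step1 ", node, " K_ex={",
                                    paste(kex, collapse = "; "), "}"))
      next
    }
    # Type II: class-origin extent of exactly two classes across ontologies,
    # K_ex strings from at most one ontology
    org <- class_origins(cpt$extent, index)
    if (nrow(org) == 2 && setequal(org$source, tags) &&
        length(kex_src) <= 1) {
      c1 <- org$iri[org$source == tags[1]]
      c2 <- org$iri[org$source == tags[2]]
      add(c1, c2, "TypeII", paste0("step1 ", node, " intent={",
                                   paste(cpt$intent, collapse = "; "), "}"))
    }
  }
  if (!length(anchors)) {
    return(data.frame(class1 = character(0), class2 = character(0),
                      type = character(0), provenance = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, anchors)
  # Type I precedence on duplicate pairs, then deterministic order
  out <- out[order(out$class1, out$class2, out$type, method = "radix"), ,
             drop = FALSE]
  out <- out[!duplicated(out[c("class1", "class2")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read anchors as TSV
#'
#' @param anchors anchor data frame (`class1`, `class2`, `type`,
#'   `provenance`).
#' @param path file path.
#' @return The path (write) or the anchor data frame (read).
#' @export
write_anchors <- function(anchors, path) {
  utils::write.table(anchors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_anchors
#' @export
read_anchors <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}
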