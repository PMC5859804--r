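#' Formal contexts
#'
#' A formal context is a triple (G, M, I): a set of objects G, a set of
#' attributes M, and a binary incidence relation I between them. Contexts are
#' the substrate of every matching step in this package; they are stored as a
#' dense logical matrix with objects in rows and attributes in columns, in
#' insertion order.
#'
#' @param objects character vector of unique object identifiers.
#' @param attributes character vector of unique attribute identifiers.
#' @param incidence either a logical matrix with `length(objects)` rows and
#'   `length(attributes)` columns, or a two-column matrix / data frame of
#'   (object, attribute) pairs.
#' @return An object of class `formal_context` with fields `objects`,
#'   `attributes` and `incidence` (named logical matrix).
#' @examples
#' ctx <- formal_context(c("o1", "o2"), c("a", "b"),
#'                       rbind(c("o1", "a"), c("o2", "b")))
#' derive_attributes(ctx, "o1")
#' @export
formal_context <- function(objects, attributes, incidence = NULL) {
  objects <- as.character(objects)
  attributes <- as.character(attributes)
  if (anyDuplicated(objects)) stop("duplicate object identifiers")
  if (anyDuplicated(attributes)) stop("duplicate attribute identifiers")
  inc <- matrix(FALSE, nrow = length(objects), ncol = length(attributes),
                dimnames = list(objects, attributes))
  if (!is.null(incidence)) {
    if (is.logical(incidence) && is.matrix(incidence)) {
      stopifnot(nrow(incidence) == length(objects),
                ncol(incidence) == length(attributes))
      inc[, ] <- incidence
    } else {
      pairs <- as.matrix(incidence)
      if (length(pairs)) {
        if (ncol(pairs) != 2) stop("incidence pairs must have two columns")
        bad_o <- setdiff(pairs[, 1], objects)
        bad_a <- setdiff(pairs[, 2], attributes)
        if (length(bad_o)) stop("incidence references unknown object: ",
                                paste(bad_o, collapse = ", "))
        if (length(bad_a)) stop("incidence references unknown attribute: ",
                                paste(bad_a, collapse = ", "))
        inc[cbind(pairs[, 1], pairs[, 2])] <- TRUE
      }
    }
  }
  structure(list(objects = objects, attributes = attributes, incidence = inc),
            class = "formal_context")
}

#' @export
print.formal_context <- function(x, ...) {
  cat(sprintf("<formal_context> %d objects x %d attributes, %d incidences\n",
              length(x$objects), length(x$attributes), sum(x$incidence)))
  invisible(x)
}

#' @export
dim.formal_context <- function(x) dim(x$incidence)

#' Derivation operators
#'
#' `derive_attributes()` maps a set of objects A to A': the attributes common
#' to every object in A. `derive_objects()` maps a set of attributes B to B':
#' the objects holding every attribute in B. By the standard convention the
#' empty set derives to the full dual set.
#'
#' @param context a `formal_context`.
#' @param object_set,attribute_set character vectors (may be empty); must be
#'   subsets of the context's objects / attributes.
#' @return A character vector, in the context's declared order.
#' @export
derive_attributes <- function(context, object_set) {
  object_set <- as.character(object_set)
  unknown <- setdiff(object_set, context$objects)
  if (length(unknown)) stop("unknown object identifier: ",
                            paste(unknown, collapse = ", "))
  if (!length(object_set)) return(context$attributes)
  rows <- context$incidence[object_set, , drop = FALSE]
  context$attributes[colSums(rows) == length(object_set)]
}

#' @rdname derive_attributes
#' @export
derive_objects <- function(context, attribute_set) {
  attribute_set <- as.character(attribute_set)
  unknown <- setdiff(attribute_set, context$attributes)
  if (length(unknown)) stop("unknown attribute identifier: ",
                            paste(unknown, collapse = ", "))
  if (!length(attribute_set)) return(context$objects)
  cols <- context$incidence[, attribute_set, drop = FALSE]
  context$objects[rowSums(cols) == length(attribute_set)]
}

#' Read and write cross-table context files
#'
#' The cross-table format is tab-separated text: the first row holds the
#' attribute names (first cell empty), each following row an object name and
#' then one cell per attribute, `"x"` where the incidence holds and empty
#' otherwise. Round-tripping a context through this format is lossless.
#'
#' @param context a `formal_context`.
#' @param path file path.
#' @return `read_context()` returns a `formal_context`; `write_context()`
#'   returns `path` invisibly.
#' @export
write_context <- function(context, path) {
  header <- paste(c("", context$attributes), collapse = "\t")
  rows <- vapply(seq_along(context$objects), function(i) {
    cells <- ifelse(context$incidence[i, ], "x", "")
    paste(c(context$objects[i], cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_context
#' @export
read_context <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty context file")
  split_keep <- function(s) strsplit(s, "\t", fixed = TRUE)[[1]]
  header <- split_keep(lines[1])
  attributes <- header[-1]
  n_cells <- length(header)
  objects <- character(0)
  pairs <- list()
  for (ln in lines[-1]) {
    cells <- split_keep(ln)
    length(cells) <- n_cells       # right-pad rows whose trailing cells are empty
    cells[is.na(cells)] <- ""
    objects <- c(objects, cells[1])
    marked <- which(cells[-1] == "x")
    if (length(marked))
      pairs[[length(pairs) + 1L]] <- cbind(cells[1], attributes[marked])
  }
  formal_context(objects, attributes, do.call(rbind, pairs))
}
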