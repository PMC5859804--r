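#' Alignment objects
#'
#' The container for a matching run's outputs: one-to-one class mappings
#' (with their type and step provenance), complex-mapping candidates,
#' property mappings, and run metadata. Serialization order is
#' deterministic and mappings are deduplicated.
#'
#' @param mappings data frame with columns `class1`, `class2`, `type`,
#'   `step`, `provenance`.
#' @param complex complex-mapping data frame (see
#'   [extract_structural_mappings()]).
#' @param property_mappings property mapping data frame.
#' @param metadata named list (source identifiers, configuration digest).
#' @return An object of class `fca_alignment`.
#' @export
fca_alignment <- function(mappings = NULL, complex = NULL,
                          property_mappings = NULL, metadata = list()) {
  empty_map <- data.frame(class1 = character(0), class2 = character(0),
                          type = character(0), step = character(0),
                          provenance = character(0), stringsAsFactors = FALSE)
  if (is.null(mappings) || !nrow(mappings)) mappings <- empty_map
  mappings <- mappings[!duplicated(mappings[c("class1", "class2")]), ,
                       drop = FALSE]
  mappings <- mappings[order(mappings$class1, mappings$class2,
                             method = "radix"), , drop = FALSE]
  rownames(mappings) <- NULL
  structure(list(mappings = mappings,
                 complex = complex,
                 property_mappings = property_mappings,
                 metadata = metadata),
            class = "fca_alignment")
}

#' @export
print.fca_alignment <- function(x, ...) {
  ncx <- if (is.null(x$complex)) 0L else nrow(x$complex)
  npm <- if (is.null(x$property_mappings)) 0L else nrow(x$property_mappings)
  cat(sprintf(
    "<fca_alignment> %d class mappings, %d complex candidates, %d property mappings\n",
    nrow(x$mappings), ncx, npm))
  if (nrow(x$mappings)) print(utils::head(x$mappings[c("class1", "class2", "type")], 10))
  invisible(x)
}

#' Write an alignment in OAEI Alignment RDF
#'
#' Emits the standard Alignment format: one `Cell` per one-to-one class
#' mapping with `relation` `"="` and constant `measure` 1.0 (the method is
#' score-free). Complex and property mappings are not part of the format;
#' use [write_alignment_tsv()] for the full record.
#'
#' @param alignment an `fca_alignment`, or a data frame with `class1` /
#'   `class2` columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment_rdf <- function(alignment, path) {
  maps <- if (inherits(alignment, "fca_alignment")) alignment$mappings
          else alignment
  cells <- unlist(lapply(seq_len(nrow(maps)), function(i) {
    c("  <map>",
      "    <Cell>",
      sprintf("      <entity1 rdf:resource=\"%s\"/>", xml_escape(maps$class1[i])),
      sprintf("      <entity2 rdf:resource=\"%s\"/>", xml_escape(maps$class2[i])),
      "      <relation>=</relation>",
      "      <measure rdf:datatype=\"http://www.w3.org/2001/XMLSchema#float\">1.0</measure>",
      "    </Cell>",
      "  </map>")
  }))
  out <- c("<?xml version=\"1.0\" encoding=\"utf-8\"?>",
           "<rdf:RDF xmlns=\"http://knowledgeweb.semanticweb.org/heterogeneity/alignment\"",
           "         xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
           "         xmlns:xsd=\"http://www.w3.org/2001/XMLSchema#\">",
           "<Alignment>",
           "  <xml>yes</xml>",
           "  <level>0</level>",
           "  <type>11</type>",
           cells,
           "</Alignment>",
           "</rdf:RDF>")
  writeLines(out, path)
  invisible(path)
}

#' Read an OAEI Alignment RDF file
#'
#' @param path alignment file path.
#' @return Data frame with columns `class1`, `class2`.
#' @export
read_alignment_rdf <- function(path) {
  doc <- xml2::read_xml(path)
  cells <- xml2::xml_find_all(doc, "//*[local-name()='Cell']")
  get_res <- function(cell, which) {
    n <- xml2::xml_find_first(cell, sprintf("./*[local-name()='%s']", which))
    xml2::xml_attr(n, "resource")
  }
  data.frame(class1 = vapply(cells, get_res, character(1), "entity1"),
             class2 = vapply(cells, get_res, character(1), "entity2"),
             stringsAsFactors = FALSE)
}

#' Write the full alignment record as TSV
#'
#' Columns: `class1`, `class2`, `type`, `step`, `provenance` for one-to-one
#' mappings, followed by complex candidates and property mappings in
#' separate sections prefixed with `#`.
#'
#' @param alignment an `fca_alignment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment_tsv <- function(alignment, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# one-to-one class mappings", con)
  utils::write.table(alignment$mappings, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(alignment$complex) && nrow(alignment$complex)) {
    writeLines("# complex mapping candidates", con)
    utils::write.table(alignment$complex, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(alignment$property_mappings) &&
      nrow(alignment$property_mappings)) {
    writeLines("# property mappings", con)
    utils::write.table(alignment$property_mappings, con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

round_half_up <- function(x, digits = 3) {
  floor(x * 10^digits + 0.5) / 10^digits
}

pair_key <- function(d) paste(d$class1, d$class2, sep = "\x1f")

#' Evaluate an alignment against a reference
#'
#' Scores the one-to-one class mappings only (complex and property mappings
#' are excluded, as reference alignments contain only class pairs). Each
#' system mapping is *correct* if present in the reference, *unknown* if
#' present in the unknown list (reference mappings whose correctness is not
#' assessed — they are ignored, counted in neither the precision denominator
#' nor the recall denominator), and *incorrect* otherwise. Precision is
#' correct / (correct + incorrect); recall is correct divided by the number
#' of reference mappings not in the unknown list; F is their harmonic mean.
#' Values are reported to three decimals, rounding half up. Duplicate system
#' mappings are collapsed before scoring.
#'
#' @param system an `fca_alignment`, a data frame with `class1` / `class2`,
#'   or a path to an Alignment RDF file.
#' @param reference reference alignment: data frame or file path.
#' @param unknown optional unknown-mapping list: data frame, file path, or
#'   `NULL`.
#' @return A list of class `eval_report` with fields `correct`, `incorrect`,
#'   `unknown`, `total`, `reference_size`, `precision`, `recall`,
#'   `f_measure`.
#' @export
evaluate <- function(system, reference, unknown = NULL) {
  as_pairs <- function(x) {
    if (is.null(x)) return(data.frame(class1 = character(0),
                                      class2 = character(0),
                                      stringsAsFactors = FALSE))
    if (is.character(x) && length(x) == 1) x <- read_alignment_rdf(x)
    if (inherits(x, "fca_alignment")) x <- x$mappings
    unique(as.data.frame(x, stringsAsFactors = FALSE)[c("class1", "class2")])
  }
  sys <- as_pairs(system); ref <- as_pairs(reference); unk <- as_pairs(unknown)
  sys_k <- pair_key(sys); ref_k <- pair_key(ref); unk_k <- pair_key(unk)
  n_unknown <- sum(sys_k %in% unk_k)
  n_correct <- sum(sys_k %in% setdiff(ref_k, unk_k))
  n_incorrect <- length(sys_k) - n_unknown - n_correct
  ref_size <- length(setdiff(ref_k, unk_k))
  if (!length(sys_k)) {
    warning("empty system alignment; precision reported as 0")
    precision <- 0
  } else if (n_correct + n_incorrect == 0) {
    precision <- 0
  } else {
    precision <- n_correct / (n_correct + n_incorrect)
  }
  recall <- if (ref_size > 0) n_correct / ref_size else 0
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall)
       else 0
  structure(list(correct = n_correct, incorrect = n_incorrect,
                 unknown = n_unknown, total = length(sys_k),
                 reference_size = ref_size,
                 precision = round_half_up(precision),
                 recall = round_half_up(recall),
                 f_measure = round_half_up(f)),
            class = "eval_report")
}

#' Build an evaluation report from printed counts
#'
#' Convenience wrapper used to reproduce published precision/recall/F values
#' from their printed contingency counts without materializing pair lists.
#'
#' @param correct,incorrect,unknown,reference_size non-negative counts;
#'   `reference_size` is the number of scored (non-unknown) reference
#'   mappings.
#' @return An `eval_report` (see [evaluate()]).
#' @export
eval_from_counts <- function(correct, incorrect, unknown = 0, reference_size) {
  mk_pair <- function(n, prefix) {
    if (n == 0) return(NULL)
    data.frame(class1 = sprintf("%s%06d_a", prefix, seq_len(n)),
               class2 = sprintf("%s%06d_b", prefix, seq_len(n)),
               stringsAsFactors = FALSE)
  }
  correct_p <- mk_pair(correct, "c")
  incorrect_p <- mk_pair(incorrect, "i")
  unknown_p <- mk_pair(unknown, "u")
  extra_ref <- mk_pair(reference_size - correct, "r")
  evaluate(system = rbind(correct_p, incorrect_p, unknown_p),
           reference = rbind(correct_p, extra_ref),
           unknown = unknown_p)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "correct %d | incorrect %d | unknown %d | total %d | reference %d\n",
    x$correct, x$incorrect, x$unknown, x$total, x$reference_size))
  cat(sprintf("precision %.3f  recall %.3f  F-measure %.3f\n",
              x$precision, x$recall, x$f_measure))
  invisible(x)
}
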