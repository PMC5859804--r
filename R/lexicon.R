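#' Token lexicons
#'
#' A token lexicon resolves token-level synonymy and lexical variation (e.g.
#' `dorsum -> back`) and carries the stop-word list used during
#' normalization. Canonical tokens always map to themselves; multi-word
#' synonyms are out of scope (whole-string synonyms enter the token context
#' as additional class lexicalizations instead).
#'
#' @param variant_map named character vector mapping variant tokens to
#'   canonical tokens (names = variants).
#' @param stop_words character vector of tokens dropped during
#'   normalization.
#' @return An object of class `token_lexicon`.
#' @export
token_lexicon <- function(variant_map = character(0),
                          stop_words = default_stop_words()) {
  variant_map <- vapply(variant_map, as.character, character(1))
  # totality: canonical targets map to themselves
  targets <- setdiff(unname(variant_map), names(variant_map))
  if (length(targets)) variant_map[targets] <- targets
  structure(list(variant_map = variant_map,
                 stop_words = unique(tolower(stop_words))),
            class = "token_lexicon")
}

#' @rdname token_lexicon
#' @export
default_stop_words <- function() {
  c("a", "an", "and", "or", "of", "the", "in", "on", "to", "with", "nos")
}

#' Read a lexicon from tab-separated files
#'
#' The variant file has two tab-separated columns (variant, canonical); the
#' stop-word file one token per line. Either may be `NULL`.
#'
#' @param variant_path,stopword_path file paths or `NULL`.
#' @return A `token_lexicon`.
#' @export
read_token_lexicon <- function(variant_path = NULL, stopword_path = NULL) {
  vm <- character(0)
  if (!is.null(variant_path)) {
    rows <- strsplit(readLines(variant_path), "\t", fixed = TRUE)
    rows <- Filter(function(r) length(r) >= 2, rows)
    vm <- setNames(vapply(rows, `[`, character(1), 2),
                   vapply(rows, `[`, character(1), 1))
  }
  sw <- if (is.null(stopword_path)) default_stop_words()
        else readLines(stopword_path)
  token_lexicon(vm, sw)
}

# Rule-based singularization; enough for ordinary English plurals
# ("Fluids" -> "fluid", "Secretions" -> "secretion", "arteries" -> "artery").
singularize <- function(tok) {
  n <- nchar(tok)
  if (n > 3 && endsWith(tok, "ies")) return(paste0(substr(tok, 1, n - 3), "y"))
  if (n > 3 && (endsWith(tok, "ses") || endsWith(tok, "xes") ||
                endsWith(tok, "zes") || endsWith(tok, "ches") ||
                endsWith(tok, "shes")))
    return(substr(tok, 1, n - 2))
  if (n > 2 && endsWith(tok, "s") && !endsWith(tok, "ss") &&
      !endsWith(tok, "us") && !endsWith(tok, "is"))
    return(substr(tok, 1, n - 1))
  tok
}

#' Normalize a string into its canonical token set
#'
#' Lowercases, splits on whitespace and punctuation (including `/`, `-` and
#' `,`), drops stop words, singularizes plurals by rule, and maps each
#' surviving token through the lexicon's variant map (iterated to a fixed
#' point so the output is canonical). Returns a sorted set: order and
#' multiplicity are discarded, and the empty set is allowed.
#'
#' @param raw a character string.
#' @param lexicon a [token_lexicon()].
#' @return Sorted character vector of canonical tokens.
#' @examples
#' normalize("Mammary Gland Fluids and Secretions", token_lexicon())
#' @export
normalize <- function(raw, lexicon = token_lexicon()) {
  toks <- strsplit(tolower(raw), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  toks <- setdiff(toks, lexicon$stop_words)
  canon <- function(t) {
    for (i in 1:5) {
      t2 <- singularize(t)
      mapped <- lexicon$variant_map[t2]
      t2 <- if (!is.na(mapped)) unname(mapped) else t2
      if (identical(t2, t)) break
      t <- t2
    }
    t
  }
  toks <- vapply(toks, canon, character(1), USE.NAMES = FALSE)
  toks <- setdiff(toks, lexicon$stop_words)
  sort(unique(toks))
}
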