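#' Structural closure queries over an ontology
#'
#' Precomputes the semantic relations the relation-based contexts consume.
#' Both asserted and inferred (transitively closed) relations are exposed:
#'
#' * `isa_ancestors(c)` / `isa_descendants(c)`: strict transitive closure of
#'   the ISA edges (a class is not its own ancestor).
#' * `partof_wholes(c)`: every whole the class is (transitively) part of,
#'   combining PART-OF edges with the taxonomy — parts are inherited by ISA
#'   descendants of the part and propagate up the whole's ISA ancestors.
#' * `siblings(c)`: classes other than `c` sharing at least one direct named
#'   superclass with `c`.
#' * `disjoint_classes(c)`: every class `d` such that some ancestor-or-self
#'   of `c` is asserted disjoint with some ancestor-or-self of `d`
#'   (disjointness is inherited downward on both sides).
#'
#' @param onto an `ontology` (its ISA graph is acyclic by construction).
#' @return A list of the five query functions, each taking a class IRI and
#'   returning a sorted character vector.
#' @export
closure_queries <- function(onto) {
  iris <- onto$classes$iri
  up <- reachability(onto$isa$sub, onto$isa$super)
  down <- reachability(onto$isa$super, onto$isa$sub)
  anc <- function(x) reach_of(up, x)
  desc <- function(x) reach_of(down, x)

  # PART-OF closure: reachability over the union graph of partof edges and
  # isa edges, keeping only targets reached through at least one partof edge.
  # part inherited downward (sub isa part => sub partof whole), whole
  # generalized upward (whole isa v => part partof v), partof transitive.
  partof_map <- local({
    if (!nrow(onto$partof)) return(list())
    pw <- list()
    # seed: each asserted edge, expanded to isa-descendants of the part
    for (k in seq_len(nrow(onto$partof))) {
      part <- onto$partof$part[k]; whole <- onto$partof$whole[k]
      wholes <- c(whole, anc(whole))
      for (p in c(part, desc(part)))
        pw[[p]] <- union(pw[[p]], wholes)
    }
    # transitivity: whole itself (or its ancestors) may be part of more
    repeat {
      grown <- FALSE
      for (p in names(pw)) {
        extra <- unique(unlist(pw[pw[[p]]], use.names = FALSE))
        new <- setdiff(extra, pw[[p]])
        if (length(new)) { pw[[p]] <- c(pw[[p]], new); grown <- TRUE }
      }
      if (!grown) break
    }
    lapply(pw, sort)
  })

  direct_parents <- function(x) unique(onto$isa$super[onto$isa$sub == x])

  disj <- onto$disjoint
  anc_or_self <- function(x) c(x, anc(x))

  list(
    isa_ancestors = function(x) sort(anc(x)),
    isa_descendants = function(x) sort(desc(x)),
    partof_wholes = function(x) {
      r <- partof_map[[x]]
      if (is.null(r)) character(0) else r
    },
    siblings = function(x) {
      ps <- direct_parents(x)
      if (!length(ps)) return(character(0))
      sibs <- unique(onto$isa$sub[onto$isa$super %in% ps])
      sort(setdiff(sibs, x))
    },
    disjoint_classes = function(x) {
      if (!nrow(disj)) return(character(0))
      ax <- anc_or_self(x)
      hit <- disj$b[disj$a %in% ax]
      hit <- c(hit, disj$a[disj$b %in% ax])
      if (!length(hit)) return(character(0))
      out <- unique(unlist(lapply(unique(hit), function(h) {
        # every class whose ancestor-or-self is h
        c(h, reach_of(down, h))
      }), use.names = FALSE))
      sort(setdiff(out, character(0)))
    }
  )
}

#' Anonymous ancestors of a class
#'
#' Closes the restriction superclass axioms under two inference rules:
#' (R1) restrictions held by any ISA ancestor of the class are inherited;
#' (R2) a held restriction `Q r.C` implies `Q r.D` for every ISA ancestor
#' `D` of the filler `C`. Entries produced only by inference carry
#' `provenance = "inferred"`; the result is deduplicated on
#' (quantifier, property, filler).
#'
#' @param onto an `ontology`.
#' @param class a class IRI of `onto`.
#' @return Data frame with columns `subject`, `quantifier`, `property`,
#'   `filler`, `provenance`, sorted deterministically.
#' @export
anonymous_ancestors <- function(onto, class) {
  if (!(class %in% onto$classes$iri))
    stop("unknown class: ", class)
  up <- reachability(onto$isa$sub, onto$isa$super)
  anc <- reach_of(up, class)
  base <- onto$restrictions
  # R1: own restrictions plus those of every ISA ancestor
  held <- base[base$subject %in% c(class, anc), , drop = FALSE]
  if (!nrow(held)) {
    return(data.frame(subject = character(0), quantifier = character(0),
                      property = character(0), filler = character(0),
                      provenance = character(0), stringsAsFactors = FALSE))
  }
  asserted_here <- base[base$subject == class & base$provenance == "asserted", ,
                        drop = FALSE]
  key <- function(d) paste(d$quantifier, d$property, d$filler, sep = "\x1f")
  out <- data.frame(quantifier = held$quantifier, property = held$property,
                    filler = held$filler, stringsAsFactors = FALSE)
  # R2: generalize fillers along their ISA ancestors, to a fixed point
  # (ancestor sets are already transitive, so one pass suffices)
  extra <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
    fa <- reach_of(up, out$filler[i])
    if (!length(fa)) return(NULL)
    data.frame(quantifier = out$quantifier[i], property = out$property[i],
               filler = fa, stringsAsFactors = FALSE)
  }))
  out <- unique(rbind(out, extra))
  out$subject <- class
  out$provenance <- ifelse(key(out) %in% key(asserted_here),
                           "asserted", "inferred")
  out <- out[c("subject", "quantifier", "property", "filler", "provenance")]
  out[order(out$property, out$quantifier, out$filler, method = "radix"), ,
      drop = FALSE]
}
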