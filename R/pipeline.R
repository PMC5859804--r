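#' Run the five-step matching pipeline
#'
#' Executes the selected matching steps in order over two ontologies:
#'
#' 1. token-based context -> lexical anchors;
#' 2. relation-based context -> evidence, conflict repair, anchor screening;
#' 3. positive relation-based context -> structural one-to-one and complex
#'    mappings;
#' 4. property-based context -> property mappings;
#' 5. restriction-based context over filler pairs -> extended one-to-one and
#'    complex mappings.
#'
#' Steps must be contiguous from 1 (each step consumes the previous step's
#' alignment). Steps 4 and 5 skip themselves with a notice when their
#' preconditions fail (no object properties, no property mappings, or an
#' empty filler-pair set). Per-step context sizes, lattice sizes and mapping
#' counts are logged as messages.
#'
#' @param onto1,onto2 `ontology` objects or paths to OWL files.
#' @param steps integer vector, a prefix of `1:5`.
#' @param lexicon a [token_lexicon()].
#' @param config a [load_config()] (used when paths are given).
#' @param quiet suppress progress messages.
#' @return An [fca_alignment()].
#' @export
run_pipeline <- function(onto1, onto2, steps = 1:5,
                         lexicon = token_lexicon(),
                         config = load_config(), quiet = FALSE) {
  steps <- sort(unique(as.integer(steps)))
  if (!length(steps) || !all(steps %in% 1:5) ||
      !identical(steps, seq_len(length(steps))))
    stop("steps must be a contiguous prefix of 1:5 (each step requires the ",
         "previous step's output)")
  if (is.character(onto1)) onto1 <- load_ontology(onto1, config, quiet = quiet)
  if (is.character(onto2)) onto2 <- load_ontology(onto2, config, quiet = quiet)
  tags <- c(onto1$tag, onto2$tag)
  say <- function(...) if (!quiet) message(sprintf(...))
  ctx_stats <- function(ctx) sprintf("|G|=%d |M|=%d |I|=%d",
                                     length(ctx$objects),
                                     length(ctx$attributes),
                                     sum(ctx$incidence))

  # Step 1 — lexical anchors
  tc <- build_token_context(onto1, onto2, lexicon)
  lat1 <- build_gsh(tc$context)
  anchors <- extract_anchors(lat1, tc$index, tags)
  anchors$step <- rep("1", nrow(anchors))
  say("step 1: token context %s, GSH %d nodes, %d anchors",
      ctx_stats(tc$context), length(lat1$concepts), nrow(anchors))
  complex_all <- NULL; prop_maps <- NULL

  # Step 2 — structural validation
  if (2 %in% steps && nrow(anchors)) {
    repaired <- repair_conflicts(onto1, onto2, anchors)
    screened <- screen_anchors(onto1, onto2, repaired)
    say("step 2: %d anchors repaired to %d, screened to %d",
        nrow(anchors), nrow(repaired), nrow(screened))
    anchors <- screened
  }

  # Step 3 — structural matching
  if (3 %in% steps && nrow(anchors)) {
    ctx3 <- build_posrel_context(onto1, onto2, anchors)
    lat3 <- build_gsh(ctx3)
    sm <- extract_structural_mappings(lat3, anchors, tags)
    sm$anchors$step <- rep("3", nrow(sm$anchors))
    say("step 3: posrel context %s, GSH %d nodes, %d new one-to-one, %d complex",
        ctx_stats(ctx3), length(lat3$concepts), nrow(sm$anchors),
        nrow(sm$complex))
    anchors <- rbind(anchors, sm$anchors)
    complex_all <- sm$complex
  }

  # Step 4 — property matching
  if (4 %in% steps && nrow(anchors)) {
    ctx4 <- build_property_context(onto1, onto2, anchors)
    if (!is.null(ctx4)) {
      lat4 <- build_gsh(ctx4)
      prop_maps <- extract_property_mappings(lat4, tags)
      say("step 4: property context %s, GSH %d nodes, %d property mappings",
          ctx_stats(ctx4), length(lat4$concepts), nrow(prop_maps))
    }
  }

  # Step 5 — restriction matching
  if (5 %in% steps && !is.null(prop_maps) && nrow(prop_maps)) {
    fp <- generate_filler_pairs(onto1, onto2, anchors, prop_maps)
    ctx5 <- build_restriction_context(fp)
    if (!is.null(ctx5)) {
      lat5 <- build_gsh(ctx5)
      rm_ <- extract_restriction_mappings(lat5)
      known <- pair_key(anchors)
      rm_$anchors <- rm_$anchors[!(pair_key(rm_$anchors) %in% known), ,
                                 drop = FALSE]
      rm_$anchors$step <- rep("5", nrow(rm_$anchors))
      say("step 5: %d filler pairs, restriction context %s, %d new one-to-one, %d complex",
          nrow(fp), ctx_stats(ctx5), nrow(rm_$anchors), nrow(rm_$complex))
      anchors <- rbind(anchors, rm_$anchors)
      complex_all <- if (is.null(complex_all)) rm_$complex else
        rbind(complex_all, rm_$complex)
    }
  } else if (5 %in% steps) {
    say("step 5 skipped: no property mappings available")
  }

  fca_alignment(mappings = anchors[c("class1", "class2", "type", "step",
                                     "provenance")],
                complex = complex_all,
                property_mappings = prop_maps,
                metadata = list(onto1 = onto1$tag, onto2 = onto2$tag,
                                steps = steps))
}
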