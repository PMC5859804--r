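rel_fx <- make_fixture("ma_nci_relations")
ma <- function(n) paste0("MA:", toy_iri("MA", n))
nc <- function(n) paste0("NCI:", toy_iri("NCI", n))
aid <- function(n1, n2) paste(toy_iri("MA", n1), toy_iri("NCI", n2), sep = "|")

test_that("the relation context reproduces the printed ten-by-five cross-table", {
  ctx <- build_relation_context(rel_fx$onto1, rel_fx$onto2, rel_fx$anchors)
  col <- function(label, n1, n2)
    derive_objects(ctx, sprintf("(%s)%s", label, aid(n1, n2)))
  expect_setequal(col("ISA", "ligament", "Ligament"),
                  c(ma("periodontal ligament"), ma("auricular ligament"),
                    ma("larynx ligament"), nc("Periodontium"),
                    nc("Broad Ligament"), nc("Laryngeal Ligament")))
  expect_setequal(col("I-D", "organ system", "Organ System"),
                  c(ma("ligament"), ma("periodontal ligament"),
                    ma("auricular ligament"), ma("adipose tissue"),
                    ma("larynx ligament"),
                    nc("Ligament"), nc("Periodontium"), nc("Broad Ligament"),
                    nc("Adipose Tissue"), nc("Laryngeal Ligament")))
  expect_setequal(col("SIB", "adipose tissue", "Adipose Tissue"),
                  ma("ligament"))
  expect_setequal(col("SIB", "larynx ligament", "Laryngeal Ligament"),
                  c(ma("periodontal ligament"), ma("auricular ligament"),
                    nc("Periodontium"), nc("Broad Ligament")))
  expect_setequal(col("PAT", "larynx", "Larynx"),
                  c(ma("larynx ligament"), nc("Laryngeal Ligament")))
  # the ten printed rows are exactly the classes marked in the printed columns
  printed <- c(sprintf("(ISA)%s", aid("ligament", "Ligament")),
               sprintf("(I-D)%s", aid("organ system", "Organ System")),
               sprintf("(SIB)%s", aid("adipose tissue", "Adipose Tissue")),
               sprintf("(SIB)%s", aid("larynx ligament", "Laryngeal Ligament")),
               sprintf("(PAT)%s", aid("larynx", "Larynx")))
  marked <- ctx$objects[rowSums(ctx$incidence[, printed, drop = FALSE]) > 0]
  expect_setequal(marked,
                  c(ma("ligament"), ma("periodontal ligament"),
                    ma("auricular ligament"), ma("adipose tissue"),
                    ma("larynx ligament"),
                    nc("Ligament"), nc("Periodontium"), nc("Broad Ligament"),
                    nc("Adipose Tissue"), nc("Laryngeal Ligament")))
  expect_error(build_relation_context(rel_fx$onto1, rel_fx$onto2,
                                      rel_fx$anchors[0, ]), "empty anchor")
})

test_that("evidence assignments match the worked ligament/organ-system example", {
  ctx <- build_relation_context(rel_fx$onto1, rel_fx$onto2, rel_fx$anchors)
  ev <- compute_evidence(ctx, rel_fx$anchors, c("MA", "NCI"))
  pl <- aid("periodontal ligament", "Periodontium")
  expect_true(pl %in% ev$P[[aid("ligament", "Ligament")]])
  expect_true(pl %in% ev$N[[aid("organ system", "Organ System")]])
  # two anchors are ISA-supported under the ligament anchor
  expect_identical(unname(ev$support[aid("ligament", "Ligament")]), 2L)
  expect_identical(unname(ev$conflict[aid("organ system", "Organ System")]),
                   4L)
  # an anchor of isolated classes has empty evidence
  iso1 <- toy_onto("MA", "island"); iso2 <- toy_onto("NCI", "Island")
  a <- toy_anchors("MA", "NCI", list(c("island", "Island")))
  ctx0 <- build_relation_context(iso1, iso2, a, drop_empty = FALSE)
  ev0 <- compute_evidence(ctx0, a, c("MA", "NCI"))
  expect_identical(unname(ev0$support), 0L)
  expect_identical(unname(ev0$conflict), 0L)
  expect_error(compute_evidence(ctx, toy_anchors("MA", "NCI",
                                                 list(c("ghost", "Ghost"))),
                                c("MA", "NCI")), "missing")
})

test_that("evidence via shared attributes equals evidence harvested from the lattice", {
  ctx <- build_relation_context(rel_fx$onto1, rel_fx$onto2, rel_fx$anchors)
  ev <- compute_evidence(ctx, rel_fx$anchors, c("MA", "NCI"))
  # lattice formulation: concepts whose extent holds both classes of anchor a
  # contribute a to P/N of every labelled anchor in their intent
  lat <- build_gsh(ctx)
  P2 <- lapply(setNames(nm = names(ev$P)), function(x) character(0))
  N2 <- P2
  aids <- names(ev$P)
  a_obj <- cbind(paste0("MA:", rel_fx$anchors$class1),
                 paste0("NCI:", rel_fx$anchors$class2))
  for (cpt in lat$concepts) {
    for (k in seq_along(aids)) {
      if (all(a_obj[k, ] %in% cpt$extent)) {
        for (attr in cpt$intent) {
          lab <- sub("^\\(([A-Z-]+)\\).*$", "\\1", attr)
          tgt <- sub("^\\([A-Z-]+\\)", "", attr)
          if (!(tgt %in% aids)) next
          if (lab %in% c("ISA", "SIB", "PAT"))
            P2[[tgt]] <- union(P2[[tgt]], aids[k])
          else N2[[tgt]] <- union(N2[[tgt]], aids[k])
        }
      }
    }
  }
  for (x in aids) {
    expect_setequal(ev$P[[x]], P2[[x]])
    expect_setequal(ev$N[[x]], N2[[x]])
  }
})

test_that("conflict repair eliminates the conflicted zero-support anchor", {
  repaired <- repair_conflicts(rel_fx$onto1, rel_fx$onto2, rel_fx$anchors)
  ids <- paste(repaired$class1, repaired$class2, sep = "|")
  expect_false(aid("organ system", "Organ System") %in% ids)
  expect_identical(nrow(repaired), 5L)
  # support 0 vs 8-style asymmetric conflicts remove the weaker anchor:
  # here the organ-system anchor (support 0) loses to all its partners
  expect_true(aid("ligament", "Ligament") %in% ids)
  expect_true(length(attr(repaired, "repair_log")) >= 1)
})

test_that("repair is a fixed point without negative evidence", {
  fx <- make_fixture("suprarenal")
  tc <- build_token_context(fx$onto1, fx$onto2)
  anc <- extract_anchors(build_gsh(tc$context), tc$index, c("MA", "NCI"))
  repaired <- repair_conflicts(fx$onto1, fx$onto2, anc)
  expect_identical(repaired$class1, anc$class1)
  expect_identical(repaired$class2, anc$class2)
})

test_that("a chained three-conflict fixture resolves as the greedy loop dictates", {
  # O1: x1 below x2 below x3, x3 asserted disjoint from x1, with 1/2/3
  # child anchors under x1/x2/x3; O2: flat y1..y3 with disjointness
  # y1|y2 and y2|y3. Hand-running the greedy loop eliminates, in order,
  # c11 (support 0), a1 (support 0 after losing c11), c21, c22 (supports
  # below a3's), then a2; a3 and its three children survive.
  o1 <- toy_onto("A",
    c("x1", "x2", "x3", "u11", "u21", "u22", "u31", "u32", "u33"),
    isa = list(c("x1", "x2"), c("x2", "x3"), c("u11", "x1"),
               c("u21", "x2"), c("u22", "x2"),
               c("u31", "x3"), c("u32", "x3"), c("u33", "x3")),
    disjoint = list(c("x3", "x1")))
  o2 <- toy_onto("B",
    c("y1", "y2", "y3", "v11", "v21", "v22", "v31", "v32", "v33"),
    isa = list(c("v11", "y1"), c("v21", "y2"), c("v22", "y2"),
               c("v31", "y3"), c("v32", "y3"), c("v33", "y3")),
    disjoint = list(c("y1", "y2"), c("y2", "y3")))
  anchors <- toy_anchors("A", "B", list(
    c("x1", "y1"), c("x2", "y2"), c("x3", "y3"),
    c("u11", "v11"), c("u21", "v21"), c("u22", "v22"),
    c("u31", "v31"), c("u32", "v32"), c("u33", "v33")))
  repaired <- repair_conflicts(o1, o2, anchors)
  ids <- paste(repaired$class1, repaired$class2, sep = "|")
  survivors <- c("x3|y3", "u31|v31", "u32|v32", "u33|v33")
  expect_setequal(ids, vapply(strsplit(survivors, "|", fixed = TRUE),
                              function(p) paste(toy_iri("A", p[1]),
                                                toy_iri("B", p[2]),
                                                sep = "|"), character(1)))
  # post-repair emptiness
  ctx <- build_relation_context(o1, o2, repaired, drop_empty = FALSE)
  ev <- compute_evidence(ctx, repaired, c("A", "B"))
  expect_true(all(ev$conflict == 0))
})

test_that("screening removes only unsupported Type II anchors", {
  repaired <- repair_conflicts(rel_fx$onto1, rel_fx$onto2, rel_fx$anchors)
  screened <- screen_anchors(rel_fx$onto1, rel_fx$onto2, repaired)
  # the Type II periodontal anchor has ISA support and survives
  expect_true(aid("periodontal ligament", "Periodontium") %in%
                paste(screened$class1, screened$class2, sep = "|"))
  # an isolated Type II anchor is dropped; an isolated Type I is retained
  o1 <- toy_onto("A", c("p", "q")); o2 <- toy_onto("B", c("P", "Q"))
  anc <- toy_anchors("A", "B", list(c("p", "P"), c("q", "Q")),
                     types = c("TypeI", "TypeII"))
  out <- screen_anchors(o1, o2, anc)
  expect_identical(out$type, "TypeI")
})

test_that("repair terminates with empty negative evidence on random conflicted fixtures", {
  set.seed(77)
  for (rep in 1:10) {
    fx <- make_fixture("random", seed = 1000 + rep,
                       params = list(n1 = 25, n2 = 25, overlap = 0.4,
                                     disjoint_rate = 0.3))
    tc <- build_token_context(fx$onto1, fx$onto2)
    anc <- extract_anchors(build_gsh(tc$context), tc$index, c("O1", "O2"))
    repaired <- repair_conflicts(fx$onto1, fx$onto2, anc)
    screened <- screen_anchors(fx$onto1, fx$onto2, repaired)
    if (nrow(screened)) {
      ctx <- build_relation_context(fx$onto1, fx$onto2, screened,
                                    drop_empty = FALSE)
      ev <- compute_evidence(ctx, screened, c("O1", "O2"))
      expect_true(all(ev$conflict == 0))
      expect_true(all(ev$support[screened$type == "TypeII"] > 0))
    }
    expect_true(nrow(screened) <= nrow(anc))
  }
})
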