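animals <- make_fixture("animals")$context

test_that("derivation operators agree with the animal cross-table", {
  expect_setequal(derive_attributes(animals, c("Dolphin", "Porpoise")),
                  c("Vertebrate", "Mammal", "Aquatic", "Carnivorous"))
  expect_setequal(derive_objects(animals, c("Vertebrate", "Mammal")),
                  c("Elephant", "Dolphin", "Porpoise"))
  # hand-intersected rows / scanned columns
  expect_setequal(derive_attributes(animals, c("Elephant", "Hawk")),
                  "Vertebrate")
  expect_setequal(derive_objects(animals, c("Carnivorous", "Flying")), "Hawk")
  # empty-set derivations return the full dual set
  expect_identical(derive_attributes(animals, character(0)),
                   animals$attributes)
  expect_identical(derive_objects(animals, character(0)), animals$objects)
})

test_that("unknown identifiers are input errors", {
  expect_error(derive_attributes(animals, "Unicorn"), "unknown object")
  expect_error(derive_objects(animals, "Invisible"), "unknown attribute")
})

test_that("brute-force enumeration finds the aquatic-mammal concept and respects closure", {
  lat <- enumerate_concepts(animals)
  cpt <- concept_with_extent(lat, c("Dolphin", "Porpoise"))
  expect_false(is.null(cpt))
  expect_setequal(cpt$intent,
                  c("Vertebrate", "Mammal", "Aquatic", "Carnivorous"))
  for (c2 in lat$concepts) {
    expect_setequal(derive_attributes(animals, c2$extent), c2$intent)
    expect_setequal(derive_objects(animals, c2$intent), c2$extent)
  }
  # unique top and bottom
  sizes <- vapply(lat$concepts, function(x) length(x$extent), integer(1))
  expect_identical(sum(sizes == length(animals$objects)), 1L)
  bottoms <- vapply(lat$concepts, function(x)
    length(x$intent) == length(animals$attributes), logical(1))
  expect_identical(sum(bottoms), 1L)
})

test_that("smallest nonempty context yields exactly the forced concepts", {
  ctx <- formal_context("o", "a", rbind(c("o", "a")))
  lat <- enumerate_concepts(ctx)
  keys <- vapply(lat$concepts, function(x)
    paste(paste(x$extent, collapse = ","), paste(x$intent, collapse = ","),
          sep = "/"), character(1))
  expect_setequal(keys, "o/a")  # ({o},{a}) is both top and bottom here
})

test_that("enumeration matches power-set closure on random contexts", {
  set.seed(101)
  for (rep in 1:5) {
    ctx <- random_context(6, 6)
    lat <- enumerate_concepts(ctx)
    oracle <- powerset_concepts(ctx)
    expect_identical(length(lat$concepts), length(oracle))
    got <- lapply(lat$concepts, function(x) sort(x$extent))
    want <- lapply(oracle, function(x) x$extent)
    expect_setequal(vapply(got, paste, character(1), collapse = "|"),
                    vapply(want, paste, character(1), collapse = "|"))
  }
})

test_that("enumeration refuses oversized contexts", {
  big <- random_context(21, 5)
  expect_error(enumerate_concepts(big), "too large")
})

test_that("Galois connection and closure idempotence hold on random contexts", {
  set.seed(202)
  for (rep in 1:20) {
    ctx <- random_context(sample(2:8, 1), sample(2:8, 1),
                          density = stats::runif(1, 0.2, 0.7))
    a <- sample(ctx$objects, sample.int(length(ctx$objects), 1))
    a2 <- derive_objects(ctx, derive_attributes(ctx, a))
    expect_true(all(a %in% a2))                       # A subset of A''
    expect_identical(sort(derive_attributes(ctx, a)),  # A' = A'''
                     sort(derive_attributes(ctx, a2)))
    a4 <- derive_objects(ctx, derive_attributes(ctx, a2))
    expect_setequal(a2, a4)                            # idempotence
    b <- sample(ctx$attributes, sample.int(length(ctx$attributes), 1))
    b2 <- derive_attributes(ctx, derive_objects(ctx, b))
    expect_true(all(b %in% b2))
  }
})

test_that("GSH equals the object/attribute concepts of the full lattice", {
  check_one <- function(ctx) {
    gsh <- build_gsh(ctx)
    full <- enumerate_concepts(ctx)
    # expected: concepts that are gamma(g) or mu(m) for some g/m
    want <- character(0)
    for (g in ctx$objects) {
      e <- derive_objects(ctx, derive_attributes(ctx, g))
      want <- union(want, paste(sort(e), collapse = "|"))
    }
    for (m in ctx$attributes) {
      e <- derive_objects(ctx, m)
      want <- union(want, paste(sort(e), collapse = "|"))
    }
    got <- vapply(gsh$concepts, function(x) paste(sort(x$extent), collapse = "|"),
                  character(1))
    expect_setequal(got, want)
    full_keys <- vapply(full$concepts, function(x)
      paste(sort(x$extent), collapse = "|"), character(1))
    expect_true(all(got %in% full_keys))
    # identical simplified labels as in the full lattice
    for (cpt in gsh$concepts) {
      twin <- concept_with_extent(full, cpt$extent)
      expect_setequal(cpt$simplified_extent, twin$simplified_extent)
      expect_setequal(cpt$simplified_intent, twin$simplified_intent)
    }
  }
  check_one(animals)
  set.seed(303)
  for (rep in 1:20) check_one(random_context(sample(2:8, 1), sample(2:8, 1)))
})

test_that("every GSH concept carries a nonempty simplified label", {
  gsh <- build_gsh(animals)
  for (cpt in gsh$concepts)
    expect_true(length(cpt$simplified_extent) > 0 ||
                  length(cpt$simplified_intent) > 0)
  # object and attribute concepts all present
  exts <- lapply(gsh$concepts, function(x) sort(x$extent))
  for (g in animals$objects) {
    e <- sort(derive_objects(animals, derive_attributes(animals, g)))
    expect_true(any(vapply(exts, identical, logical(1), e)))
  }
})

test_that("lattice order follows extent containment both ways", {
  set.seed(404)
  ctx <- random_context(6, 6)
  lat <- enumerate_concepts(ctx)
  n <- length(lat$concepts)
  ord <- matrix(FALSE, n, n)
  if (nrow(lat$order)) ord[lat$order] <- TRUE
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ci <- lat$concepts[[i]]; cj <- lat$concepts[[j]]
    le_ext <- all(ci$extent %in% cj$extent) &&
      !setequal(ci$extent, cj$extent)
    ge_int <- all(cj$intent %in% ci$intent) &&
      !setequal(ci$intent, cj$intent)
    expect_identical(ord[i, j], le_ext)
    expect_identical(le_ext, ge_int)
  }
})

test_that("lattice construction and serialization are deterministic", {
  set.seed(505)
  ctx <- random_context(7, 7)
  expect_identical(format_lattice(build_gsh(ctx)),
                   format_lattice(build_gsh(ctx)))
  expect_identical(format_lattice(enumerate_concepts(ctx)),
                   format_lattice(enumerate_concepts(ctx)))
})

test_that("cross-table serialization round-trips losslessly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_context(animals, path)
  back <- read_context(path)
  expect_identical(back$objects, animals$objects)
  expect_identical(back$attributes, animals$attributes)
  expect_identical(back$incidence, animals$incidence)
  # a context with an all-empty row survives too
  ctx <- formal_context(c("x", "y"), c("m"), rbind(c("x", "m")))
  write_context(ctx, path)
  expect_identical(read_context(path)$incidence, ctx$incidence)
})
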