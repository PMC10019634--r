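test_that("OBO parsing handles chains, multi-parent stanzas and obsolete terms", {
  path <- obo_text(
    "[Term]", "id: R", "name: root", "",
    "[Term]", "id: A", "name: a", "is_a: R", "",
    "[Term]", "id: B", "name: b", "is_a: A", ""
  )
  g <- read_obo(path)
  expect_setequal(g$terms, c("R", "A", "B"))
  expect_equal(g$root, "R")
  expect_equal(g$parents$B, "A")

  path2 <- obo_text(
    "[Term]", "id: R", "",
    "[Term]", "id: A", "is_a: R", "",
    "[Term]", "id: C", "is_a: R", "",
    "[Term]", "id: D", "is_a: A ! with comment", "is_a: C", "",
    "[Term]", "id: X", "is_a: R", "is_obsolete: true", ""
  )
  g2 <- read_obo(path2)
  expect_setequal(g2$parents$D, c("A", "C"))
  expect_false("X" %in% g2$terms)
})

test_that("OBO parsing rejects cycles, multiple roots, unknown parents", {
  cyc <- obo_text(
    "[Term]", "id: A", "is_a: B", "",
    "[Term]", "id: B", "is_a: A", ""
  )
  expect_error(read_obo(cyc), "cycle|root")
  two_roots <- obo_text(
    "[Term]", "id: R1", "",
    "[Term]", "id: R2", "",
    "[Term]", "id: A", "is_a: R1", ""
  )
  expect_error(read_obo(two_roots), "multiple parentless")
  bad_parent <- obo_text(
    "[Term]", "id: R", "",
    "[Term]", "id: A", "is_a: ZZZ", ""
  )
  expect_error(read_obo(bad_parent), "unknown parent")
})

test_that("propagation computes the reflexive ancestor closure", {
  g <- chain_graph()
  expect_setequal(propagate(g, "B"), c("B", "A", "R"))
  expect_equal(propagate(g, "R"), "R")
  gd <- diamond_graph()
  expect_setequal(propagate(gd, "D"), c("D", "A", "C", "R"))
  expect_error(propagate(g, "nope"), "unknown term")
})

test_that("propagation is idempotent and monotone on random DAGs", {
  for (seed in 1:5) {
    g <- generate_ontology(40, 3, seed = seed)
    set.seed(seed)
    raw <- sample(g$terms, 4)
    p1 <- propagate(g, raw)
    expect_identical(propagate(g, p1), p1)
    bigger <- propagate(g, c(raw, sample(g$terms, 2)))
    expect_true(all(p1 %in% bigger))
    expect_true(g$root %in% p1)
  }
})

test_that("information content follows -log2 of term frequency", {
  g <- diamond_graph()
  corpus <- list(
    term_set("v1", "D", g),      # D, A, C, R
    term_set("v2", "B", g),      # B, A, R
    term_set("v3", "A", g),      # A, R
    term_set("v4", "C", g)       # C, R
  )
  ic <- information_content(corpus)
  expect_equal(unname(ic$ic["R"]), 0)            # in all sets
  expect_equal(unname(ic$ic["B"]), 2)            # 1 of 4
  expect_equal(unname(ic$ic["C"]), 1)            # 2 of 4
  expect_equal(unname(ic$ic["A"]), -log2(3 / 4)) # 3 of 4
  expect_error(information_content(list()), "empty")
})

test_that("IC is non-increasing from child to parent after propagation", {
  g <- generate_ontology(60, 3, seed = 9)
  corpus <- lapply(1:30, function(i) {
    set.seed(100 + i)
    term_set(paste0("v", i), sample(g$terms, 3), g)
  })
  ic <- information_content(corpus)
  for (t in names(ic$ic)) {
    for (p in g$parents[[t]]) {
      if (p %in% names(ic$ic)) expect_lte(ic$ic[[p]], ic$ic[[t]] + 1e-12)
    }
  }
})

test_that("MICA picks the most informative common ancestor with deterministic ties", {
  g <- diamond_graph()
  corpus <- list(
    term_set("v1", "D", g),
    term_set("v2", "B", g),
    term_set("v3", "A", g),
    term_set("v4", "C", g)
  )
  ic <- information_content(corpus)
  ## reflexive: mica(t, t) = t
  m <- mica(g, ic, "D", "D")
  expect_equal(m$term, "D")
  expect_equal(m$ic, 2)
  ## common ancestors of D and B are {A, R}; IC(A) > IC(R)
  expect_equal(mica(g, ic, "D", "B")$term, "A")
  ## B and C share only the root
  mr <- mica(g, ic, "B", "C")
  expect_equal(mr$term, "R")
  expect_equal(mr$ic, 0)
  ## ties broken lexicographically: craft equal-IC common ancestors
  g2 <- ontology_graph(list(R = character(0), A = "R", C = "R", D = c("A", "C")))
  corpus2 <- list(term_set("v1", "D", g2), term_set("v2", "R", g2))
  ic2 <- information_content(corpus2)  # A, C, D all in 1 of 2 sets: IC 1 each
  tie <- mica(g2, ic2, "D", "D")
  expect_equal(tie$term, "A")  # lexicographically smallest among equal-IC {A, C, D}
  expect_equal(tie$ic, 1)
  expect_equal(mica(g2, ic2, "A", "C")$term, "R")
})

test_that("set similarity matches hand-computed values", {
  g <- diamond_graph()
  sA <- term_set("a", "B", g)           # {B, A, R}
  sB <- term_set("b", "C", g)           # {C, R}
  ## jaccard on propagated sets: share {R} of {B, A, C, R}
  expect_equal(set_similarity("jaccard", sA, sB, g), 1 / 4)
  expect_equal(set_similarity("jaccard", sA, sA, g), 1)
  corpus <- list(sA, sB, term_set("c", "D", g))
  ic <- information_content(corpus)
  ## self-similarity: resnik = IC of the term; lin = 1 when IC > 0
  sD <- corpus[[3]]
  expect_equal(set_similarity("resnik", sD, sD, g, ic), unname(ic$ic["D"]))
  expect_equal(set_similarity("lin", sD, sD, g, ic), 1)
  ## resnik(B-set, C-set) = IC(MICA(B, C)) = IC(R) = 0
  expect_equal(set_similarity("resnik", sA, sB, g, ic), 0)
  ## symmetry
  expect_equal(
    set_similarity("lin", sA, sB, g, ic),
    set_similarity("lin", sB, sA, g, ic)
  )
  expect_error(set_similarity("jaccard", list(), list(), g), "empty|list")
})

test_that("similarity_matrix equals entrywise set_similarity calls", {
  set.seed(42)
  g <- generate_ontology(40, 3, seed = 2)
  corpus <- random_corpus(6, g)
  ic <- information_content(corpus)
  for (measure in c("jaccard", "resnik", "lin")) {
    S <- similarity_matrix(measure, corpus, g, ic = ic)
    expect_true(isSymmetric(unclass(S), tol = 1e-12))
    for (i in 1:6) {
      for (j in 1:6) {
        expect_equal(
          S[i, j],
          set_similarity(measure, corpus[[i]], corpus[[j]], g, ic),
          tolerance = 1e-12,
          info = paste(measure, i, j)
        )
      }
    }
  }
})

test_that("jaccard matrices over propagated sets are PSD; lin entries bounded", {
  for (seed in 1:20) {
    set.seed(seed)
    g <- generate_ontology(30, 3, seed = seed)
    corpus <- random_corpus(10, g)
    S <- similarity_matrix("jaccard", corpus, g)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * sum(diag(S)))
  }
  g <- generate_ontology(40, 3, seed = 77)
  set.seed(77)
  corpus <- random_corpus(12, g)
  ic <- information_content(corpus)
  L <- similarity_matrix("lin", corpus, g, ic = ic)
  expect_true(all(L >= -1e-12 & L <= 1 + 1e-12))
  R <- similarity_matrix("resnik", corpus, g, ic = ic)
  expect_true(all(R >= -1e-12))
})

test_that("IC-based matrices can be indefinite and the check detects it", {
  found_indefinite <- FALSE
  for (seed in 1:20) {
    g <- generate_ontology(50, 3, seed = seed)
    set.seed(seed + 500)
    corpus <- random_corpus(15, g)
    ic <- information_content(corpus)
    for (measure in c("resnik", "lin")) {
      S <- similarity_matrix(measure, corpus, g, ic = ic)
      if (!check_psd(S)$psd) found_indefinite <- TRUE
    }
    if (found_indefinite) break
  }
  expect_true(found_indefinite)
})
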