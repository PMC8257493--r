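test_that("parse_obo builds the expected DAG from small inputs", {
  two <- parse_obo(c("[Term]", "id: A", "name: a",
                     "[Term]", "id: B", "name: b", "is_a: A ! a"),
                   phenotype_root = NULL)
  expect_equal(sort(two$terms$term), c("A", "B"))
  expect_equal(two$parents[["B"]], "A")
  expect_equal(two$root, "A")

  multi <- toy_ontology(list(P1 = "R", P2 = "R", L = c("P1", "P2")))
  expect_setequal(multi$parents[["L"]], c("P1", "P2"))
})

test_that("bundled mini ontology has 30 terms, one root and no cycles", {
  onto <- parse_obo(mini_hpo_path())
  expect_equal(sum(!onto$terms$obsolete), 30)
  expect_length(onto$root, 1)
  # brute-force check: no term is its own proper ancestor
  for (t in names(onto$ancestors)) {
    anc <- brute_ancestors(onto, t)
    expect_false(t %in% setdiff(anc, t))
  }
  # every term reaches the root
  expect_true(all(vapply(names(onto$ancestors),
                         function(t) onto$root %in% brute_ancestors(onto, t),
                         logical(1))))
})

test_that("parse_obo rejects cycles and dangling targets, keeps obsolete inert", {
  expect_error(parse_obo(c("[Term]", "id: A", "name: a", "is_a: B",
                           "[Term]", "id: B", "name: b", "is_a: A"),
                         phenotype_root = NULL),
               "cyclic")
  expect_error(parse_obo(c("[Term]", "id: A", "name: a", "is_a: ZZ"),
                         phenotype_root = NULL),
               "unknown term")
  obs <- parse_obo(c("[Term]", "id: A", "name: a",
                     "[Term]", "id: B", "name: b", "is_obsolete: true"),
                   phenotype_root = NULL)
  expect_true(obs$terms$obsolete[obs$terms$term == "B"])
  expect_error(ancestor_closure(obs, "B"), "unknown")
})

test_that("alt_id annotations are canonicalized with a message", {
  onto <- parse_obo(mini_hpo_path())
  expect_message(out <- resolve_terms(onto, "HP:0002279"), "canonicalized")
  expect_equal(out, "HP:0001250")
  expect_error(resolve_terms(onto, "HP:9999999"), "unknown")
})

test_that("closures match brute-force reachability on chains, diamonds and random DAGs", {
  ch <- chain4()
  expect_setequal(ancestor_closure(ch, "T4"), c("T1", "T2", "T3", "T4"))
  expect_setequal(descendant_closure(ch, "T1"), c("T1", "T2", "T3", "T4"))
  expect_equal(ancestor_closure(ch, "T1"), "T1")
  expect_equal(descendant_closure(ch, "T4"), "T4")

  dm <- diamond4()
  expect_setequal(ancestor_closure(dm, "L"), c("L", "P1", "P2", "R"))
  expect_setequal(descendant_closure(dm, "R"), c("R", "P1", "P2", "L"))

  for (seed in 1:10) {
    onto <- generate_ontology(sample(10:50, 1), depth = 4, branching = 3,
                              extra_parent_p = 0.3, seed = seed)
    terms <- sample(names(onto$ancestors), 3)
    for (t in terms) {
      expect_setequal(ancestor_closure(onto, t), brute_ancestors(onto, t))
      expect_setequal(descendant_closure(onto, t), brute_descendants(onto, t))
    }
    # monotonicity in the query set
    s2 <- sample(names(onto$ancestors), 5)
    s1 <- s2[1:2]
    expect_true(all(ancestor_closure(onto, s1) %in% ancestor_closure(onto, s2)))
  }
})

test_that("ancestor_closure is idempotent and errors on unknown terms", {
  onto <- parse_obo(mini_hpo_path())
  cl <- ancestor_closure(onto, c("HP:0012469", "HP:0002072"))
  expect_setequal(ancestor_closure(onto, cl), cl)
  expect_error(ancestor_closure(onto, "HP:1234567"), "HP:1234567")
})

test_that("term frequencies and information content follow -log2(f)", {
  ann <- tibble::tibble(
    individual_id = c(sprintf("I%03d", 1:413), "I001"),
    term = c(rep("HP:0000001", 413), "HP:0099999")
  )
  fr <- term_frequencies(ann, n = 413)
  expect_equal(fr$ic[fr$term == "HP:0000001"], 0)
  expect_equal(fr$f[fr$term == "HP:0000001"], 1)
  # singleton in a 413 cohort: the maximal IC
  expect_equal(fr$ic[fr$term == "HP:0099999"], -log2(1 / 413), tolerance = 1e-12)
  expect_equal(round(fr$ic[fr$term == "HP:0099999"], 2), 8.69)

  fr2 <- term_frequencies(
    tibble::tibble(individual_id = c("a", "a", "b", "c"),
                   term = c("X", "X", "Y", "Y")), n = 4)
  expect_equal(fr2$ic[fr2$term == "X"], 2)  # f = 0.25, duplicate collapsed

  expect_error(term_frequencies(ann, n = 0), "n must be")
})

test_that("mica returns the maximal-IC common ancestor with deterministic ties", {
  onto <- parse_obo(mini_hpo_path())
  base <- tibble::tibble(
    individual_id = c("a", "b", "c", "d"),
    term = c("HP:0012469", "HP:0011097", "HP:0001250", "HP:0012638"),
    polarity = "positive")
  harm <- harmonize_cohort(onto, base)
  fr <- term_frequencies(harm[harm$polarity == "positive", ], n = 4)

  # a term subsuming another is its own MICA
  m <- mica(onto, fr, "HP:0001250", "HP:0012469")
  expect_equal(m$term, "HP:0001250")
  expect_equal(m$ic, -log2(3 / 4))
  # self-MICA
  m2 <- mica(onto, fr, "HP:0012469", "HP:0012469")
  expect_equal(m2$ic, -log2(1 / 4))
  # symmetry
  expect_equal(mica(onto, fr, "HP:0012469", "HP:0011097")$ic,
               mica(onto, fr, "HP:0011097", "HP:0012469")$ic)
  # incomplete frequency table is a hard error, not a fallback
  expect_error(mica(onto, fr[fr$term != "HP:0000001", ],
                    "HP:0012469", "HP:0011097"), "missing")
})

test_that("mica agrees with exhaustive common-ancestor enumeration on diamonds", {
  dm <- toy_ontology(list(P1 = "R", P2 = "R", L1 = c("P1", "P2"),
                          L2 = c("P1", "P2")))
  # frequencies making P2 the more informative shared ancestor
  ann <- tibble::tibble(
    individual_id = c("a", "a", "a", "b", "b", "c", "d"),
    term = c("P1", "P2", "R", "P1", "R", "P1", "R"))
  fr <- term_frequencies(ann, n = 4)
  fr <- dplyr::bind_rows(fr, tibble::tibble(term = c("L1", "L2"),
                                            count = 1, f = 0.25, ic = 2))
  got <- mica(dm, fr, "L1", "L2")
  common <- intersect(brute_ancestors(dm, "L1"), brute_ancestors(dm, "L2"))
  ics <- fr$ic[match(common, fr$term)]
  expect_equal(got$ic, max(ics))
  expect_equal(got$term, "P2")
})

test_that("write_obo round-trips a generated ontology", {
  onto <- generate_ontology(40, seed = 3, extra_parent_p = 0.2)
  f <- withr::local_tempfile(fileext = ".obo")
  write_obo(onto, f)
  onto2 <- parse_obo(f, phenotype_root = NULL)
  expect_setequal(onto2$terms$term, onto$terms$term)
  expect_equal(onto2$parents[names(onto$parents)], onto$parents)
})
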