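test_that("positive propagation is the ancestor closure and is idempotent", {
  ch <- chain4()
  expect_setequal(propagate_positive(ch, "T4"), c("T1", "T2", "T3", "T4"))
  expect_equal(propagate_positive(ch, character(0)), character(0))
  p <- propagate_positive(ch, "T3")
  expect_setequal(propagate_positive(ch, p), p)
  expect_error(propagate_positive(ch, "NOPE"), "unknown")

  onto <- parse_obo(mini_hpo_path())
  base <- c("HP:0012469", "HP:0002521")
  prop <- propagate_positive(onto, base)
  expect_true(all(base %in% prop))
  expect_gte(length(prop), length(base))
})

test_that("negative propagation descends and is blocked by positives", {
  onto <- parse_obo(mini_hpo_path())
  # leaf: stays put
  expect_equal(propagate_negative(onto, "HP:0002126"), "HP:0002126")
  # node with two leaf children, no positives below
  expect_setequal(propagate_negative(onto, "HP:0012443"),
                  c("HP:0012443", "HP:0000252", "HP:0002126"))
  # positively annotated child blocks the subsuming node but not the
  # sibling branch
  pos <- propagate_positive(onto, "HP:0000252")  # Microcephaly positive
  got <- propagate_negative(onto, "HP:0012443", pos)
  expect_false("HP:0012443" %in% got)  # subsumes a positive
  expect_false("HP:0000252" %in% got)  # is the positive
  expect_true("HP:0002126" %in% got)   # untouched sibling branch
  # asserting absence of a directly asserted positive term is a conflict
  expect_error(
    propagate_negative(onto, "HP:0000252", pos, base_pos = "HP:0000252",
                       individual_id = "P7"),
    "conflict.*P7.*HP:0000252")
})

test_that("pruning keeps apex terms only and is lossless", {
  ch <- chain4()
  full <- propagate_negative(ch, "T1")
  expect_setequal(full, c("T1", "T2", "T3", "T4"))
  expect_equal(prune_negative(ch, full), "T1")
  expect_equal(prune_negative(ch, "T4"), "T4")
  expect_equal(prune_negative(ch, character(0)), character(0))

  onto <- parse_obo(mini_hpo_path())
  # two disjoint negative subtrees -> two apexes
  full2 <- propagate_negative(onto, c("HP:0012443", "HP:0011097"))
  pruned2 <- prune_negative(onto, full2)
  expect_setequal(pruned2, c("HP:0012443", "HP:0011097"))
})

test_that("negative propagate -> prune -> re-propagate round-trips losslessly", {
  for (seed in 1:8) {
    onto <- generate_ontology(sample(15:50, 1), depth = 4, branching = 3,
                              extra_parent_p = 0.25, seed = seed)
    pool <- setdiff(names(onto$ancestors), onto$root)
    set.seed(seed)
    pos <- propagate_positive(onto, sample(pool, 3))
    neg_base <- sample(setdiff(pool, pos), 4)
    full <- propagate_negative(onto, neg_base, pos)
    pruned <- prune_negative(onto, full)
    expect_true(all(pruned %in% full))
    back <- propagate_negative(onto, pruned, pos)
    expect_setequal(back, full)
  }
})

test_that("harmonize_cohort enforces the annotation-set invariants", {
  mc <- mini_cohort(n = 15, seed = 4)
  h <- harmonize_cohort(mc$onto, mc$annotations)
  for (id in unique(h$individual_id)) {
    hi <- h[h$individual_id == id, ]
    pos <- hi$term[hi$polarity == "positive"]
    base_pos <- hi$term[hi$polarity == "positive" & hi$origin == "base"]
    neg_any <- hi$term[hi$polarity == "negative"]
    expect_true(all(base_pos %in% pos))
    expect_gte(length(pos), length(base_pos))
    # positive set closed under ancestors
    expect_setequal(ancestor_closure(mc$onto, pos), pos)
    # no term both positive and negative
    expect_length(intersect(pos, neg_any), 0)
    # pruned negatives are a subset of the full negatives
    expect_true(all(hi$term[hi$polarity == "negative" & hi$in_pruned] %in%
                      neg_any))
  }
})

test_that("propagated ancestor frequency equals fraction of individuals with a base descendant", {
  mc <- mini_cohort(n = 25, seed = 11)
  h <- harmonize_cohort(mc$onto, mc$annotations)
  pos <- h[h$polarity == "positive", ]
  fr <- term_frequencies(pos, n = 25)
  base_sets <- split(pos$term[pos$origin == "base"],
                     pos$individual_id[pos$origin == "base"])
  for (t in sample(fr$term, 8)) {
    desc <- descendant_closure(mc$onto, t)
    recount <- sum(vapply(base_sets, function(s) any(s %in% desc), logical(1)))
    expect_equal(fr$count[fr$term == t], recount)
  }
})

test_that("NP: shorthand and polarity columns are read correctly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("individual_id\tterm",
               "P1\tHP:0001250",
               "P1\tNP:0000717"), f)
  ann <- read_annotations(f)
  expect_equal(ann$term, c("HP:0001250", "HP:0000717"))
  expect_equal(ann$polarity, c("positive", "negative"))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("individual_id\tterm\tpolarity",
               "P1\tHP:0001250\tnegative",
               "P1\tHP:0000717\tbogus"), f2)
  expect_error(read_annotations(f2), "polarity")
})

test_that("base-vs-propagated frequency shift matches the hypergeometric oracle", {
  base <- tibble::tibble(term = c("A", "B"), count = c(5, 50), f = 0, ic = 0)
  prop <- tibble::tibble(term = c("A", "B"), count = c(200, 50), f = 0, ic = 0)
  out <- compare_term_frequencies(base, prop, n = 413, q = 0.1)
  expect_equal(out$p[out$term == "A"], brute_fisher_p(5, 408, 200, 213),
               tolerance = 1e-10)
  expect_equal(out$p[out$term == "B"], 1)
  expect_true(out$significant[out$term == "A"])
  expect_false(out$significant[out$term == "B"])
  expect_error(compare_term_frequencies(base, prop, n = 40), "cohort size")
})
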