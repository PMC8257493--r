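make_freqs <- function(onto, n_ind = 20, seed = 5) {
  set.seed(seed)
  pool <- names(onto$ancestors)
  ann <- dplyr::bind_rows(lapply(seq_len(n_ind), function(i) {
    base <- sample(setdiff(pool, onto$root), sample(2:4, 1))
    tibble::tibble(individual_id = paste0("I", i),
                   term = ancestor_closure(onto, base))
  }))
  term_frequencies(ann, n = n_ind)
}

test_that("individual similarity: self, disjoint branches, symmetry, root invariance", {
  onto <- parse_obo(mini_hpo_path())
  mc <- mini_cohort(n = 20, seed = 5)
  h <- harmonize_cohort(onto, mc$annotations)
  pos <- h[h$polarity == "positive", ]
  fr <- term_frequencies(pos, n = 20)

  A <- ancestor_closure(onto, "HP:0012469")
  B <- ancestor_closure(onto, "HP:0002126")

  # self-similarity is the IC sum of the set
  expect_equal(individual_similarity(onto, fr, A, A),
               sum(fr$ic[match(A, fr$term)]))
  # symmetry
  expect_equal(individual_similarity(onto, fr, A, B),
               individual_similarity(onto, fr, B, A))
  # adding the root never changes the score
  expect_equal(individual_similarity(onto, fr, c(A, onto$root), B),
               individual_similarity(onto, fr, A, B))
  # directional sum never exceeds self-similarity
  expect_lte(individual_similarity(onto, fr, A, B),
             max(individual_similarity(onto, fr, A, A),
                 individual_similarity(onto, fr, B, B)))
  # empty set: zero with warning
  expect_warning(s0 <- individual_similarity(onto, fr, character(0), B))
  expect_equal(s0, 0)
})

test_that("sets sharing only IC-0 ancestors score zero", {
  onto <- toy_ontology(list(A = "R", B = "R", A1 = "A", B1 = "B"))
  # every individual carries R and A (f = 1 -> IC 0); branch B distinguishes
  ann <- tibble::tibble(
    individual_id = c("x", "x", "x", "y", "y", "y", "y"),
    term = c("R", "A", "A1", "R", "A", "B", "B1"))
  fr <- term_frequencies(ann, n = 2)
  expect_equal(individual_similarity(onto, fr, c("A1", "A", "R"),
                                     c("B1", "B", "R")), 0)
})

test_that("pairwise similarity equals the exhaustive double-loop oracle", {
  for (seed in 1:4) {
    onto <- generate_ontology(40, depth = 4, branching = 3,
                              extra_parent_p = 0.25, seed = seed)
    fr <- make_freqs(onto, seed = seed)
    set.seed(seed + 100)
    for (rep in 1:25) {
      a <- sample(fr$term, sample(2:4, 1))
      b <- sample(fr$term, sample(2:3, 1))
      expect_equal(individual_similarity(onto, fr, a, b),
                   brute_similarity(onto, fr, a, b), tolerance = 1e-12)
    }
  }
})

test_that("similarity_matrix agrees with pairwise calls and is symmetric", {
  mc <- mini_cohort(n = 10, seed = 3)
  h <- harmonize_cohort(mc$onto, mc$annotations)
  pos <- h[h$polarity == "positive", ]
  fr <- term_frequencies(pos, n = 10)
  sim <- similarity_matrix(h, mc$onto, fr)
  expect_true(isSymmetric(sim))
  sets <- split(pos$term, pos$individual_id)
  for (pair in list(c(1, 2), c(3, 7), c(5, 10))) {
    i <- rownames(sim)[pair[1]]; j <- rownames(sim)[pair[2]]
    expect_equal(sim[i, j],
                 individual_similarity(mc$onto, fr, sets[[i]], sets[[j]]),
                 tolerance = 1e-12)
  }
})

test_that("group permutation test obeys the add-one p formula and reproducibility", {
  mc <- mini_cohort(n = 20, seed = 13)
  h <- harmonize_cohort(mc$onto, mc$annotations)
  sim <- similarity_matrix(h, mc$onto)
  ids <- rownames(sim)

  # a clone-like group beats every permutation: p = 1/(N+1)
  clone_sim <- sim
  g <- ids[1:4]
  clone_sim[g, g] <- max(sim) * 10
  res <- group_similarity_test(clone_sim, g, n_perm = 200, seed = 1)
  expect_equal(res$p, 1 / 201)
  expect_gte(res$p, 1 / (res$n_perm + 1))

  # determinism under a fixed seed
  r1 <- group_similarity_test(sim, ids[3:8], n_perm = 300, seed = 42)
  r2 <- group_similarity_test(sim, ids[3:8], n_perm = 300, seed = 42)
  expect_identical(r1, r2)

  expect_error(group_similarity_test(sim, ids[1]), "at least 2")
  expect_error(group_similarity_test(sim, ids), "proper subset")
  expect_error(group_similarity_test(sim, c(ids[1:2], "ghost")), "ghost")
})

test_that("phenograms compare group and remainder frequencies", {
  mc <- mini_cohort(n = 16, seed = 9)
  h <- harmonize_cohort(mc$onto, mc$annotations)
  ids <- unique(h$individual_id)
  g <- ids[1:5]
  # plant a group-specific term
  planted <- tibble::tibble(individual_id = g, term = "HP:0002126",
                            polarity = "positive", origin = "base",
                            in_pruned = TRUE)
  h2 <- dplyr::bind_rows(h[!(h$term == "HP:0002126" &
                               h$polarity == "positive"), ], planted)
  ph <- phenogram(h2, g)
  expect_true(ph$highlight[ph$term == "HP:0002126"])
  expect_equal(ph$freq_group[ph$term == "HP:0002126"], 1)
  # the root is carried by everyone: p = 1, not highlighted
  root_row <- ph[ph$term == mc$onto$root, ]
  expect_equal(root_row$p, 1)
  expect_false(root_row$highlight)

  expect_error(phenogram(h, ids), "proper subset")
  expect_error(phenogram(h, character(0)), "non-empty")
})

test_that("the similarity suite books groups correctly and skips singletons", {
  onto <- generate_ontology(60, seed = 31)
  coh <- generate_cohort(
    cohort_config(seed = 31, n_missense = 30, n_ptv = 10, n_other = 1,
                  recurrent_sizes = c(5, 3, 2), n_gof = 3,
                  n_lof_missense = 3), onto)
  h <- harmonize_cohort(onto, coh$annotations)
  sim <- similarity_matrix(h, onto)
  suppressMessages(
    suite <- run_similarity_suite(sim, coh$variants, n_perm = 100, seed = 2))
  rec <- suite[suite$family == "recurrent_variant", ]
  expect_equal(sort(rec$n, decreasing = TRUE)[1:3], c(5, 3, 2))
  expect_true(all(suite$n >= 2))
  expect_setequal(intersect(unique(suite$family),
                            c("broad_class", "recurrent_variant")),
                  c("broad_class", "recurrent_variant"))
  # identical seed reproduces the whole suite
  suppressMessages(
    suite2 <- run_similarity_suite(sim, coh$variants, n_perm = 100, seed = 2))
  expect_identical(suite, suite2)
})
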