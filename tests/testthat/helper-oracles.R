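# Independent oracles and hand-built fixtures. Everything here is
# deliberately brute-force and shares no code path with the package
# implementation it checks.

# ontology from an explicit parent list, e.g. list(B = "A", C = c("A", "B"))
toy_ontology <- function(parent_list, root = NULL) {
  ids <- unique(c(names(parent_list), unlist(parent_list), root))
  obo <- c("format-version: 1.2", unlist(lapply(ids, function(t) {
    ps <- parent_list[[t]]
    c("", "[Term]", paste0("id: ", t), paste0("name: name ", t),
      if (length(ps)) paste0("is_a: ", ps))
  })))
  parse_obo(paste(obo, collapse = "\n"), phenotype_root = NULL)
}

# 4-term chain T4 -> T3 -> T2 -> T1 (root)
chain4 <- function() {
  toy_ontology(list(T2 = "T1", T3 = "T2", T4 = "T3"))
}

# diamond: leaf L with parents P1, P2 sharing grandparent R
diamond4 <- function() {
  toy_ontology(list(P1 = "R", P2 = "R", L = c("P1", "P2")))
}

# brute-force transitive closure by boolean matrix powers
brute_ancestors <- function(onto, term) {
  ids <- names(onto$ancestors)
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))  # A[i,j]: j parent of i
  for (t in ids) A[t, onto$parents[[t]]] <- TRUE
  reach <- A
  repeat {
    nxt <- ((reach %*% A) > 0) | reach
    if (all(nxt == reach)) break
    reach <- nxt
  }
  unique(c(term, ids[reach[term, ]]))
}

brute_descendants <- function(onto, term) {
  ids <- names(onto$ancestors)
  down <- ids[vapply(ids, function(t) term %in% brute_ancestors(onto, t),
                     logical(1))]
  unique(c(term, down))
}

# exhaustive two-sided Fisher p by enumeration over tables with fixed margins
brute_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, c1, r1 + r2 - c1, r1)
  obs <- stats::dhyper(a, c1, r1 + r2 - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# exhaustive pairwise concordance AUC
brute_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  gr <- outer(pos, neg, `>`)
  eq <- outer(pos, neg, `==`)
  (sum(gr) + 0.5 * sum(eq)) / (length(pos) * length(neg))
}

# exhaustive double-loop best-match similarity using mica() directly
brute_similarity <- function(onto, freqs, a, b) {
  best <- function(x, ys) max(vapply(ys, function(y) {
    mica(onto, freqs, x, y)$ic
  }, numeric(1)))
  s_ab <- sum(vapply(a, best, numeric(1), ys = b))
  s_ba <- sum(vapply(b, best, numeric(1), ys = a))
  (s_ab + s_ba) / 2
}

# small harmonized cohort on the bundled mini ontology
mini_cohort <- function(n = 20, seed = 99) {
  onto <- parse_obo(mini_hpo_path())
  set.seed(seed)
  pool <- setdiff(names(onto$ancestors), onto$root)
  ann <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    pos <- sample(pool, sample(2:5, 1))
    neg_pool <- setdiff(pool, ancestor_closure(onto, pos))
    neg <- if (length(neg_pool)) sample(neg_pool, min(2, length(neg_pool)))
           else character(0)
    tibble::tibble(individual_id = sprintf("P%02d", i),
                   term = c(pos, neg),
                   polarity = rep(c("positive", "negative"),
                                  c(length(pos), length(neg))))
  }))
  list(onto = onto, annotations = ann)
}
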