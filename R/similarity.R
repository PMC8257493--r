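#' Resnik-style similarity of two individuals' term sets
#'
#' The similarity of a term pair is the information content of their most
#' informative common ancestor (MICA). The directional score of set A
#' against set B sums, over the terms of A, each term's best match in B;
#' the reported score is the arithmetic mean of the two directional sums,
#' which is symmetric and makes self-similarity comparable across set
#' sizes. The alternative symmetrization (the plain sum of both directions)
#' is available via `symmetrize = "sum"`.
#'
#' @inheritParams mica
#' @param a,b Character vectors: propagated positive term sets.
#' @param symmetrize `"mean"` (default) or `"sum"`.
#' @return A single non-negative number; 0 when the sets share only
#'   IC-0 ancestors (e.g. the root), or when either set is empty (with a
#'   warning, since such individuals are excluded from group tests).
#' @export
individual_similarity <- function(onto, freqs, a, b, symmetrize = c("mean", "sum")) {
  symmetrize <- match.arg(symmetrize)
  if (length(a) == 0L || length(b) == 0L) {
    warning("empty term set; similarity 0")
    return(0)
  }
  terms <- unique(c(a, b))
  micam <- mica_ic_matrix(onto, freqs, terms)
  block <- micam[unique(a), unique(b), drop = FALSE]
  s_ab <- sum(apply(block, 1, max))
  s_ba <- sum(apply(block, 2, max))
  if (symmetrize == "mean") (s_ab + s_ba) / 2 else s_ab + s_ba
}

#' All-pairs similarity matrix for a cohort
#'
#' Computes the [individual_similarity()] score for every pair of
#' individuals, sharing one MICA information-content lookup across the
#' whole cohort. Group permutation tests and the similarity suite operate
#' on this matrix.
#'
#' @inheritParams mica
#' @param harmonized Output of [harmonize_cohort()]; only propagated
#'   positive terms enter the score.
#' @param symmetrize Passed to the pairwise score; see
#'   [individual_similarity()].
#' @return A symmetric numeric matrix with individual ids as dimnames and
#'   self-similarities on the diagonal.
#' @export
similarity_matrix <- function(harmonized, onto, freqs = NULL,
                              symmetrize = c("mean", "sum")) {
  symmetrize <- match.arg(symmetrize)
  pos <- harmonized[harmonized$polarity == "positive", ]
  if (is.null(freqs)) freqs <- term_frequencies(pos)
  sets <- split(pos$term, pos$individual_id)
  ids <- names(sets)
  terms <- unique(unlist(sets, use.names = FALSE))
  micam <- mica_ic_matrix(onto, freqs, terms)
  idx <- lapply(sets, match, table = terms)
  n <- length(ids)
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    ii <- idx[[i]]
    for (j in i:n) {
      blk <- micam[ii, idx[[j]], drop = FALSE]
      s <- sum(apply(blk, 1, max)) + sum(apply(blk, 2, max))
      out[i, j] <- out[j, i] <- if (symmetrize == "mean") s / 2 else s
    }
  }
  out
}

#' Permutation test of within-group phenotypic similarity
#'
#' The observed statistic is the median of all pairwise similarities within
#' the group. The null distribution draws the same number of individuals
#' uniformly without replacement from the whole cohort (the group's own
#' members included) and recomputes the median, `n_perm` times. The p-value
#' uses the add-one formula `p = (1 + #[null >= observed]) / (n_perm + 1)`,
#' so it can never be zero and is bounded below by `1/(n_perm + 1)`.
#'
#' @param sim Similarity matrix from [similarity_matrix()].
#' @param members Character vector of individual ids (at least 2, fewer
#'   than the cohort).
#' @param n_perm Number of permutations (default 100000).
#' @param seed Optional integer seed for a reproducible null.
#' @param label Group label stored in the result.
#' @return A one-row tibble: `group`, `n`, `observed`, `n_perm`, `p`,
#'   `seed`.
#' @export
group_similarity_test <- function(sim, members, n_perm = 1e5, seed = NULL,
                                  label = "group") {
  ids <- rownames(sim)
  if (!all(members %in% ids)) {
    stop("unknown individual id(s): ",
         paste(setdiff(members, ids), collapse = ", "), call. = FALSE)
  }
  n <- length(unique(members))
  if (n < 2L) stop("group must have at least 2 members", call. = FALSE)
  if (n >= length(ids)) stop("group must be a proper subset of the cohort",
                             call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  obs <- median_pairwise(sim, match(unique(members), ids))
  null <- vapply(seq_len(n_perm), function(i) {
    median_pairwise(sim, sample.int(length(ids), n))
  }, numeric(1))
  tibble::tibble(group = label, n = n, observed = obs, n_perm = n_perm,
                 p = (1 + sum(null >= obs)) / (n_perm + 1),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

median_pairwise <- function(sim, idx) {
  s <- sim[idx, idx]
  stats::median(s[upper.tri(s)])
}

#' Phenogram: per-term frequency comparison of a subgroup against the rest
#'
#' For every propagated term, compares its frequency inside the group with
#' the remainder of the cohort by a two-sided Fisher exact test. Terms with
#' uncorrected p below the threshold are highlighted, matching the usual
#' phenogram rendering.
#'
#' @param harmonized Output of [harmonize_cohort()].
#' @param group_ids Character vector of individual ids; must be a non-empty
#'   proper subset of the cohort.
#' @param threshold Uncorrected p-value highlight threshold (default 0.05).
#' @param polarity Annotation polarity to tabulate (default positive).
#' @return A tibble: `term`, `freq_group`, `freq_rest`, `p`, `highlight`.
#' @export
phenogram <- function(harmonized, group_ids, threshold = 0.05,
                      polarity = "positive") {
  ids <- unique(harmonized$individual_id)
  group_ids <- unique(group_ids)
  if (length(group_ids) == 0L || !all(group_ids %in% ids)) {
    stop("group must be a non-empty subset of the cohort", call. = FALSE)
  }
  if (length(group_ids) == length(ids)) {
    stop("group must be a proper subset of the cohort", call. = FALSE)
  }
  pol <- polarity
  df <- harmonized |> dplyr::filter(.data$polarity %in% pol)
  n_g <- length(group_ids); n_r <- length(ids) - n_g
  counts <- df |>
    dplyr::distinct(.data$individual_id, .data$term) |>
    dplyr::mutate(in_group = .data$individual_id %in% group_ids) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(a = sum(.data$in_group), c_ = sum(!.data$in_group))
  counts$p <- purrr::map2_dbl(counts$a, counts$c_, function(a, c_) {
    fisher_2x2(a, n_g - a, c_, n_r - c_)$p
  })
  counts |>
    dplyr::transmute(.data$term,
                     freq_group = .data$a / n_g,
                     freq_rest = .data$c_ / n_r,
                     p = .data$p,
                     highlight = .data$p < threshold)
}

#' Similarity suite over variant classes, locations and recurrent variants
#'
#' Runs one [group_similarity_test()] per (a) broad variant class,
#' (b) domain (DI-DIV) and segment class (S1-S6, pooled across domains) of
#' missense carriers, (c) recurrent variant carried by two or more
#' individuals, and (d) missense carriers excluding the S5-S6 pore loop.
#' Groups with fewer than two members are skipped with a message.
#'
#' @param sim Similarity matrix from [similarity_matrix()].
#' @param variants Variant tibble from [read_variants()] (with topology
#'   columns for the location groups).
#' @param n_perm Permutations per test.
#' @param seed Optional integer; the suite derives one sub-seed per group so
#'   results do not depend on the order in which groups run.
#' @return A tibble of [group_similarity_test()] rows with a `family`
#'   column (`broad_class`, `domain`, `segment`, `recurrent_variant`,
#'   `composite`).
#' @export
run_similarity_suite <- function(sim, variants, n_perm = 1e5, seed = NULL) {
  ids <- rownames(sim)
  v <- variants[variants$individual_id %in% ids, ]
  if (!"broad_class" %in% names(v)) v$broad_class <- broad_class(v$var_class)
  mis <- v[v$broad_class == "missense", ]

  groups <- list()
  add <- function(groups, family, label, members) {
    members <- intersect(unique(members), ids)
    if (length(members) < 2L) {
      message("group ", label, " has fewer than 2 members; skipped")
      return(groups)
    }
    if (length(members) >= length(ids)) {
      message("group ", label, " spans the whole cohort; skipped")
      return(groups)
    }
    c(groups, list(list(family = family, label = label, members = members)))
  }
  for (bc in unique(v$broad_class)) {
    groups <- add(groups, "broad_class", bc,
                  v$individual_id[v$broad_class == bc])
  }
  if ("domain" %in% names(v)) {
    for (d in c("DI", "DII", "DIII", "DIV")) {
      groups <- add(groups, "domain", d,
                    mis$individual_id[!is.na(mis$domain) & mis$domain == d])
    }
    for (s in paste0("S", 1:6)) {
      groups <- add(groups, "segment", s,
                    mis$individual_id[!is.na(mis$segment) & mis$segment == s])
    }
    groups <- add(groups, "composite", "missense_excl_pore_loop",
                  mis$individual_id[is.na(mis$pore_loop) | !mis$pore_loop])
  }
  rec <- table(v$hgvs_p[v$broad_class != "other"])
  for (lab in names(rec[rec >= 2])) {
    groups <- add(groups, "recurrent_variant", lab,
                  v$individual_id[!is.na(v$hgvs_p) & v$hgvs_p == lab])
  }
  if (length(groups) == 0L) stop("no testable groups", call. = FALSE)

  sub_seeds <- if (is.null(seed)) rep(list(NULL), length(groups)) else {
    set.seed(seed)
    as.list(sample.int(.Machine$integer.max, length(groups)))
  }
  purrr::map2(groups, sub_seeds, function(g, s) {
    res <- group_similarity_test(sim, g$members, n_perm = n_perm, seed = s,
                                 label = g$label)
    res$family <- g$family
    res
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$p, .data$group)
}
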