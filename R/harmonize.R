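#' Read a per-individual annotation table
#'
#' Reads a tab-separated annotation file with columns `individual_id`,
#' `term` and optionally `polarity`. Terms written with the `NP:` shorthand
#' prefix are converted to their `HP:` id with negative polarity; an explicit
#' `polarity` column (`"positive"`/`"negative"`) overrides the prefix.
#'
#' @param file Path to a TSV file.
#' @return A tibble with columns `individual_id`, `term`, `polarity`.
#' @export
read_annotations <- function(file) {
  df <- readr::read_tsv(file, show_col_types = FALSE, comment = "#")
  if (!all(c("individual_id", "term") %in% names(df))) {
    stop("annotation table needs columns individual_id, term", call. = FALSE)
  }
  np <- startsWith(df$term, "NP:")
  if (!"polarity" %in% names(df)) {
    df$polarity <- ifelse(np, "negative", "positive")
  } else {
    df$polarity <- dplyr::coalesce(df$polarity,
                                   ifelse(np, "negative", "positive"))
  }
  df$term <- ifelse(np, sub("^NP:", "HP:", df$term), df$term)
  bad <- setdiff(unique(df$polarity), c("positive", "negative"))
  if (length(bad)) stop("invalid polarity value(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  tibble::as_tibble(df[c("individual_id", "term", "polarity")])
}

#' Upward propagation of positive annotations
#'
#' Expands a set of directly assigned ("base") positive terms with every
#' applicable higher-level term up to the ontology root. This is the ancestor
#' closure of the base set, and is idempotent.
#'
#' @inheritParams ancestor_closure
#' @param base_pos Character vector of base positive term ids.
#' @return Character vector: the propagated positive set.
#' @export
propagate_positive <- function(onto, base_pos) {
  ancestor_closure(onto, base_pos)
}

#' Downward propagation of negative annotations
#'
#' An asserted absent phenotype implies the absence of every more specific
#' phenotype below it, so negative terms propagate downward. Propagation is
#' blocked wherever it would contradict a positive assertion: any term that
#' is itself positively annotated, or has a positive descendant, is excluded
#' (an individual observed to have a specific seizure type cannot be
#' "negative" for any ancestor of that seizure type).
#'
#' @inheritParams ancestor_closure
#' @param base_neg Character vector of base negative term ids.
#' @param prop_pos The individual's propagated positive set (used to block
#'   contradictions).
#' @param base_pos The individual's directly asserted positive terms. A base
#'   negative term that is also a base positive is a curation conflict and
#'   raises an error; conflicts that arise only through propagation are
#'   blocked silently.
#' @param individual_id Optional id used in conflict error messages.
#' @return Character vector: the fully propagated negative set.
#' @export
propagate_negative <- function(onto, base_neg, prop_pos = character(0),
                               base_pos = character(0), individual_id = NULL) {
  if (length(base_neg) == 0L) return(character(0))
  check_known(onto, base_neg)
  conflict <- intersect(base_neg, base_pos)
  if (length(conflict)) {
    stop("negative assertion conflicts with positive annotation",
         if (!is.null(individual_id)) paste0(" for individual ", individual_id),
         ": ", paste(conflict, collapse = ", "), call. = FALSE)
  }
  full <- descendant_closure(onto, base_neg)
  # a term contradicts a positive iff it is a positive term or an ancestor of
  # one; the ancestor closure of the positives covers both cases
  pos_anc <- if (length(prop_pos)) ancestor_closure(onto, prop_pos) else character(0)
  setdiff(full, pos_anc)
}

#' Prune a propagated negative set to its apex terms
#'
#' Downward propagation over a large ontology yields many redundant negative
#' terms. Pruning cuts each negative region at its apex: a term is retained
#' only if none of its parents is also negative. The removed terms are fully
#' recoverable by re-running downward propagation from the apexes, so the
#' compression is lossless.
#'
#' @inheritParams ancestor_closure
#' @param neg_full Character vector: output of [propagate_negative()].
#' @return Character vector: the apex (pruned) negative set.
#' @export
prune_negative <- function(onto, neg_full) {
  if (length(neg_full) == 0L) return(character(0))
  check_known(onto, neg_full)
  keep <- vapply(neg_full,
                 function(t) !any(onto$parents[[t]] %in% neg_full),
                 logical(1))
  neg_full[keep]
}

#' Harmonize a cohort's annotations
#'
#' Runs positive upward propagation, negative downward propagation and
#' negative pruning for every individual, returning one long tibble of
#' harmonized annotations.
#'
#' @inheritParams ancestor_closure
#' @param annotations A tibble as returned by [read_annotations()]:
#'   columns `individual_id`, `term`, `polarity`. Alternate ids are
#'   canonicalized.
#' @return A tibble of class `phen_annotations` with columns
#'   `individual_id`, `term`, `polarity`, `origin` (`"base"` or
#'   `"propagated"`) and `in_pruned` (`TRUE` for every positive term and for
#'   negative terms retained by pruning).
#' @examples
#' onto <- parse_obo(mini_hpo_path())
#' ann <- tibble::tibble(individual_id = "P1",
#'                       term = "HP:0012469", polarity = "positive")
#' harmonize_cohort(onto, ann)
#' @export
harmonize_cohort <- function(onto, annotations) {
  annotations <- annotations |>
    dplyr::mutate(term = resolve_terms(onto, .data$term)) |>
    dplyr::distinct(.data$individual_id, .data$term, .data$polarity)

  per_ind <- split(annotations, annotations$individual_id)
  rows <- purrr::map(per_ind, function(df) {
    base_pos <- df$term[df$polarity == "positive"]
    base_neg <- df$term[df$polarity == "negative"]
    prop_pos <- propagate_positive(onto, base_pos)
    neg_full <- propagate_negative(onto, base_neg, prop_pos, base_pos,
                                   individual_id = df$individual_id[1])
    neg_pruned <- prune_negative(onto, neg_full)
    tibble::tibble(
      individual_id = df$individual_id[1],
      term = c(prop_pos, neg_full),
      polarity = rep(c("positive", "negative"),
                     c(length(prop_pos), length(neg_full))),
      origin = c(ifelse(prop_pos %in% base_pos, "base", "propagated"),
                 ifelse(neg_full %in% base_neg, "base", "propagated")),
      in_pruned = c(rep(TRUE, length(prop_pos)), neg_full %in% neg_pruned)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("phen_annotations", class(out))
  out
}

#' Binary phenotype matrix from harmonized annotations
#'
#' @param harmonized Output of [harmonize_cohort()].
#' @param polarity Which annotations to include as columns: `"positive"`,
#'   `"negative"` or both. Negative-term columns are named with the `NP:`
#'   shorthand prefix so they never collide with positive columns.
#' @param pruned_negatives Use only the pruned (apex) negative set
#'   (default `TRUE`).
#' @param individuals Optional character vector fixing row order (and
#'   including annotation-free individuals as all-zero rows).
#' @return A logical matrix, individuals x terms.
#' @export
phen_matrix <- function(harmonized, polarity = c("positive", "negative"),
                        pruned_negatives = TRUE, individuals = NULL) {
  pol <- polarity
  df <- harmonized |>
    dplyr::filter(.data$polarity %in% pol) |>
    dplyr::filter(.data$polarity == "positive" | .data$in_pruned | !pruned_negatives) |>
    dplyr::mutate(col = ifelse(.data$polarity == "negative",
                               sub("^HP:", "NP:", .data$term), .data$term))
  if (is.null(individuals)) individuals <- sort(unique(harmonized$individual_id))
  cols <- sort(unique(df$col))
  m <- matrix(FALSE, length(individuals), length(cols),
              dimnames = list(individuals, cols))
  m[cbind(match(df$individual_id, individuals), match(df$col, cols))] <- TRUE
  m
}

#' Compare base and propagated term frequencies
#'
#' For every base term, tests whether propagation significantly shifted its
#' cohort frequency: a two-sided Fisher exact test on the 2x2 table of
#' (base carriers, non-carriers) versus (propagated carriers, non-carriers),
#' with Benjamini-Hochberg control at FDR `q` across all base terms.
#'
#' @param base,propagated Frequency tables from [term_frequencies()]
#'   computed on the same cohort (base and propagated states).
#' @param n Cohort size (must match both tables).
#' @param q FDR level (default 0.1).
#' @return A tibble with columns `term`, `count_base`, `count_propagated`,
#'   `p`, `significant`, sorted by `p`.
#' @export
compare_term_frequencies <- function(base, propagated, n, q = 0.1) {
  if (any(base$count > n) || any(propagated$count > n)) {
    stop("counts exceed cohort size n; tables and n must match", call. = FALSE)
  }
  out <- base |>
    dplyr::select("term", count_base = "count") |>
    dplyr::left_join(propagated |> dplyr::select("term", count_propagated = "count"),
                     by = "term") |>
    dplyr::mutate(count_propagated = dplyr::coalesce(.data$count_propagated,
                                                     .data$count_base))
  out$p <- purrr::map2_dbl(out$count_base, out$count_propagated, function(a, b) {
    fisher_2x2(a, n - a, b, n - b)$p
  })
  out$significant <- bh_fdr(out$p, q)
  dplyr::arrange(out, .data$p, .data$term)
}
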