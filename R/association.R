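#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact two-sided p-value (summation of hypergeometric probabilities no
#' larger than that of the observed table), conditional maximum-likelihood
#' odds ratio and exact 95% confidence interval. Tables with a zero cell
#' yield point estimates of 0 or `Inf` with one finite confidence bound.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `(a, b)` = carriers/non-carriers in the first group,
#'   `(c, d)` = carriers/non-carriers in the second group.
#' @param conf_level Confidence level for the exact interval (default 0.95).
#' @return A list with elements `p`, `or`, `ci_low`, `ci_high` and
#'   `or_sample` (the unconditional sample odds ratio `ad/bc`, reported for
#'   transparency).
#' @examples
#' fisher_2x2(5, 5, 5, 5)  # p = 1, OR = 1
#' @export
fisher_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("negative cell count", call. = FALSE)
  if (sum(cells) < 1) stop("empty 2x2 table", call. = FALSE)
  ft <- stats::fisher.test(matrix(cells, 2, 2, byrow = TRUE),
                           conf.level = conf_level)
  list(p = min(unname(ft$p.value), 1),  # guard fp overshoot above 1
       or = unname(ft$estimate),
       ci_low = ft$conf.int[1],
       ci_high = ft$conf.int[2],
       or_sample = (a * d) / (b * c))
}

#' Benjamini-Hochberg FDR flags
#'
#' Step-up procedure at level `q`; the returned flags are invariant to the
#' input order of the p-values.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param q FDR level.
#' @return Logical vector: `TRUE` where the hypothesis is rejected.
#' @export
bh_fdr <- function(p, q = 0.1) {
  if (length(p) == 0L) return(logical(0))
  if (any(p <= 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH") <= q
}

#' Term-wise association of a phenotype matrix with a binary grouping
#'
#' Runs one two-sided Fisher exact test per term column on the 2x2 table of
#' carriers/non-carriers inside and outside the group, with one
#' Benjamini-Hochberg correction across all tested terms.
#'
#' @param mat Logical/0-1 matrix, individuals x terms (positive columns
#'   `HP:`, pruned negative columns `NP:`; see [phen_matrix()]).
#' @param group Logical vector (length `nrow(mat)`) or character vector of
#'   row names defining the in-group. Both groups must be non-empty.
#' @param q FDR level (default 0.1).
#' @param analysis Label stored in the output (e.g. `"missense_vs_PTV"`).
#' @return A tibble with one row per term: `term`, `polarity`, `p`, `or`,
#'   `or_sample`, `ci_low`, `ci_high`, `freq_in_group`, `freq_out_group`,
#'   `direction` (`"in_group"` if the term is enriched in the group),
#'   `significant`, `analysis`; sorted by `p`.
#' @export
associate <- function(mat, group, q = 0.1, analysis = "association") {
  if (is.character(group)) group <- rownames(mat) %in% group
  stopifnot(length(group) == nrow(mat))
  n_in <- sum(group); n_out <- sum(!group)
  if (n_in == 0L || n_out == 0L) stop("both groups must be non-empty",
                                      call. = FALSE)
  a <- colSums(mat[group, , drop = FALSE])
  c_ <- colSums(mat[!group, , drop = FALSE])
  res <- purrr::map2(a, c_, function(ai, ci) {
    fisher_2x2(ai, n_in - ai, ci, n_out - ci)
  })
  out <- tibble::tibble(
    term = colnames(mat),
    polarity = ifelse(startsWith(colnames(mat), "NP:"), "negative", "positive"),
    p = unname(purrr::map_dbl(res, "p")),
    or = unname(purrr::map_dbl(res, "or")),
    or_sample = unname(purrr::map_dbl(res, "or_sample")),
    ci_low = unname(purrr::map_dbl(res, "ci_low")),
    ci_high = unname(purrr::map_dbl(res, "ci_high")),
    freq_in_group = unname(a / n_in),
    freq_out_group = unname(c_ / n_out),
    direction = unname(ifelse(a / n_in >= c_ / n_out,
                              "in_group", "out_group")),
    analysis = analysis
  )
  out$significant <- bh_fdr(out$p, q)
  dplyr::arrange(out, .data$p, .data$term)
}

#' Associations of phenotype terms with missense variant locations
#'
#' For every topology location (each domain DI-DIV, each segment class
#' S1-S6 pooled across domains, and the derived S5-S6 pore-loop flag),
#' compares carriers of a missense variant at that location against all
#' other missense carriers, term by term. Multiple-testing correction is
#' applied once across the full location x term family; per-location flags
#' are also reported.
#'
#' @param variants Variant tibble from [read_variants()] with topology
#'   columns; only missense rows are used.
#' @param mat Phenotype matrix (see [phen_matrix()]); rows are matched to
#'   `variants$individual_id`.
#' @param q FDR level (default 0.1).
#' @return A tibble of [associate()] rows with an extra `location` column;
#'   `significant` is the pooled-family flag and `significant_within` the
#'   per-location flag. Locations with no carriers are skipped with a
#'   message.
#' @export
location_associations <- function(variants, mat, q = 0.1) {
  mis <- variants[variants$broad_class == "missense" & !is.na(variants$position), ]
  mis <- mis[mis$individual_id %in% rownames(mat), ]
  if (nrow(mis) < 2L) stop("need at least two located missense carriers",
                           call. = FALSE)
  m <- mat[mis$individual_id, , drop = FALSE]

  groups <- c(
    stats::setNames(lapply(c("DI", "DII", "DIII", "DIV"),
                           function(d) !is.na(mis$domain) & mis$domain == d),
                    c("DI", "DII", "DIII", "DIV")),
    stats::setNames(lapply(paste0("S", 1:6),
                           function(s) !is.na(mis$segment) & mis$segment == s),
                    paste0("S", 1:6)),
    list(pore_loop = !is.na(mis$pore_loop) & mis$pore_loop)
  )

  res <- purrr::imap(groups, function(g, nm) {
    if (sum(g) == 0L || sum(!g) == 0L) {
      message("location ", nm, " has no informative split; skipped")
      return(NULL)
    }
    r <- associate(m, g, q = q, analysis = "location")
    r$significant_within <- r$significant
    r$location <- nm
    r
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) stop("no location had members", call. = FALSE)
  out$significant <- bh_fdr(out$p, q)
  dplyr::arrange(out, .data$p, .data$location, .data$term)
}
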