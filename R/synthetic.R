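#' Generate a random rooted phenotype-ontology DAG
#'
#' Builds a synthetic ontology by levels: each term draws one parent
#' uniformly from the level above and, with probability `extra_parent_p`,
#' one additional parent from any strictly shallower level. Parents always
#' sit at shallower levels, so the graph is acyclic by construction.
#'
#' @param n_terms Total number of terms including the root.
#' @param depth Maximum depth (levels below the root).
#' @param branching Target number of children per term; level `l` holds up
#'   to `branching^l` terms.
#' @param extra_parent_p Probability of a second parent (DAG-ness).
#' @param seed Optional integer seed.
#' @return An [`ontology`][parse_obo] object with terms `HP:9xxxxxx`.
#' @export
generate_ontology <- function(n_terms, depth = 5, branching = 3,
                              extra_parent_p = 0.1, seed = NULL) {
  if (n_terms < 1) stop("n_terms must be >= 1", call. = FALSE)
  if (n_terms > 1 && branching < 1) {
    stop("branching must be >= 1 for more than one term", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("HP:%07d", 9000000 + seq_len(n_terms))
  level <- integer(n_terms)  # root at level 0
  if (n_terms > 1) {
    capacity <- cumsum(branching^(seq_len(depth)))
    lv <- vapply(seq_len(n_terms - 1), function(i) {
      which(capacity >= i)[1]
    }, integer(1))
    if (anyNA(lv)) lv[is.na(lv)] <- depth  # overflow piles into the deepest level
    level[-1] <- lv
  }
  parents <- stats::setNames(vector("list", n_terms), ids)
  parents[[1]] <- character(0)
  for (i in seq_len(n_terms)[-1]) {
    above <- ids[level == level[i] - 1L]
    p <- sample(above, 1)
    if (stats::runif(1) < extra_parent_p && level[i] > 1L) {
      shallower <- setdiff(ids[level < level[i]], c(p, ids[1]))
      if (length(shallower)) p <- c(p, sample(shallower, 1))
    }
    parents[[ids[i]]] <- p
  }
  build_ontology(
    terms = tibble::tibble(term = ids,
                           name = paste("Synthetic term", seq_len(n_terms)),
                           obsolete = FALSE),
    parents = parents
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the statistical structure of a literature-curated
#' cohort of an ion-channel disorder: 413 individuals split 341 missense /
#' 68 protein-truncating / 4 other; a median of 6 base positive terms per
#' individual; negative assertions in about 63% of individuals (1-7 terms,
#' median 2); one term planted at odds ratio 8 between the two broad
#' variant classes; recurrent-variant subgroups sharing a homogeneous core
#' of base terms; and a latent gain-/loss-of-function factor expressed in
#' dedicated term choices with a 1.5-SD class separation.
#'
#' @param n_missense,n_ptv,n_other Broad-class group sizes.
#' @param base_lambda Base positive term count per individual is
#'   `1 + Poisson(base_lambda)`; the default 5 targets a median of 6.
#' @param focus_weight Sampling weight multiplier for terms inside an
#'   individual's randomly chosen focus subtree (1 = uniform sampling,
#'   under which expected term frequencies are analytic).
#' @param neg_rate Probability that an individual carries any negative
#'   assertions.
#' @param neg_lambda Negative count is `min(1 + Poisson(neg_lambda), 7)`;
#'   the default 1.3 targets a median of 2.
#' @param planted_or Odds ratio planted on one term between missense and
#'   PTV carriers (`NULL` or 1 for no effect).
#' @param planted_freq Carrier frequency of the planted term in the
#'   out-group (PTV).
#' @param recurrent_sizes Sizes of recurrent-variant groups (each shares a
#'   core of `core_terms` base terms carried with probability `core_p`).
#' @param core_terms,core_p Size and penetrance of each recurrent group's
#'   shared term core (`core_p = 0` disables the cores).
#' @param n_gof,n_lof_missense Numbers of missense variants with GoF and
#'   LoF functional evidence.
#' @param class_delta Separation (in SD units) of the GoF and LoF latent
#'   factor means (`0` disables the class structure).
#' @param n_class_terms Number of GoF-linked and of LoF-linked terms.
#' @param seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_missense = 341, n_ptv = 68, n_other = 4,
                          base_lambda = 5, focus_weight = 4,
                          neg_rate = 260 / 413, neg_lambda = 1.3,
                          planted_or = 8, planted_freq = 0.15,
                          recurrent_sizes = c(18, 14, 10, 5, 5, 3, 3, 2, 2),
                          core_terms = 4, core_p = 0.8,
                          n_gof = 17, n_lof_missense = 20,
                          class_delta = 1.5, n_class_terms = 6,
                          seed = 1L) {
  stopifnot(neg_rate >= 0, neg_rate <= 1, core_p >= 0, core_p <= 1,
            is.null(planted_or) || planted_or > 0)
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic annotated cohort with planted effects
#'
#' Samples base positive terms per individual from branch-biased
#' distributions over the supplied ontology, injects a class-linked term at
#' the configured odds ratio, assigns recurrent-variant groups sharing a
#' homogeneous term core, ties GoF/LoF labels to a latent factor expressed
#' in dedicated term choices, and generates non-contradictory negative
#' assertions. All randomness is governed by `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param onto An [`ontology`][parse_obo], typically from
#'   [generate_ontology()].
#' @return A list with elements `annotations` (tibble: `individual_id`,
#'   `term`, `polarity`), `variants` (tibble: `individual_id`, `hgvs_p`,
#'   `var_class`, `phenotype_group`), `evidence` (tibble: `hgvs_p`,
#'   `functional`) and `truth` (list recording every planted effect,
#'   per-individual base counts and the sampling pool, sufficient to
#'   compute expected term frequencies in the no-effect configuration).
#' @export
generate_cohort <- function(config, onto) {
  cf <- config
  set.seed(cf$seed)
  n <- cf$n_missense + cf$n_ptv + cf$n_other
  if (sum(cf$recurrent_sizes) > cf$n_missense) {
    stop("planted recurrent groups exceed the missense group", call. = FALSE)
  }
  ids <- sprintf("IND%04d", seq_len(n))
  broad <- rep(c("missense", "PTV", "other"),
               c(cf$n_missense, cf$n_ptv, cf$n_other))

  pool <- setdiff(names(onto$ancestors), onto$root)
  depth1 <- onto$children[[onto$root[1]]]

  # reserved terms for planted effects; leaves only, so that carrier status
  # after propagation equals the planted draw exactly (an internal term
  # would also be reached from background descendants, diluting the
  # planted odds ratio)
  leaves <- pool[lengths(onto$children[pool]) == 0L]
  reserve_n <- 1 + 2 * cf$n_class_terms +
    length(cf$recurrent_sizes) * cf$core_terms
  if (reserve_n >= length(leaves)) {
    stop("ontology too small for the configured effects", call. = FALSE)
  }
  reserved <- sample(leaves, reserve_n)
  planted_term <- reserved[1]
  gof_terms <- reserved[1 + seq_len(cf$n_class_terms)]
  lof_terms <- reserved[1 + cf$n_class_terms + seq_len(cf$n_class_terms)]
  core_pool <- reserved[-(seq_len(1 + 2 * cf$n_class_terms))]
  cores <- split(core_pool, rep(seq_along(cf$recurrent_sizes),
                                each = cf$core_terms))

  # variants -----------------------------------------------------------
  rand_label <- function(k, stop_codon = FALSE) {
    aa <- setdiff(unname(AA3), "*")
    paste0("p.", sample(aa, k, TRUE), sample(50:1950, k),
           if (stop_codon) "*" else sample(aa, k, TRUE))
  }
  hgvs <- character(n)
  mis_idx <- which(broad == "missense")
  rec_members <- list()
  used <- 0
  for (g in seq_along(cf$recurrent_sizes)) {
    sz <- cf$recurrent_sizes[g]
    members <- mis_idx[used + seq_len(sz)]
    used <- used + sz
    hgvs[members] <- rand_label(1)
    rec_members[[g]] <- ids[members]
  }
  rest <- if (used > 0) mis_idx[-seq_len(used)] else mis_idx
  hgvs[rest] <- rand_label(length(rest))
  ptv_idx <- which(broad == "PTV")
  hgvs[ptv_idx] <- rand_label(length(ptv_idx), stop_codon = TRUE)
  other_idx <- which(broad == "other")
  hgvs[other_idx] <- NA_character_
  var_class <- character(n)
  var_class[mis_idx] <- "missense"
  var_class[ptv_idx] <- sample(c("nonsense", "frameshift", "splice site",
                                 "deletion"), length(ptv_idx), TRUE,
                               prob = c(27, 27, 13, 1))
  var_class[other_idx] <- sample(c("in-frame deletion", "duplication",
                                   "complex indel"), length(other_idx), TRUE)

  # GoF/LoF evidence on unique (non-recurrent) missense variants
  singleton <- setdiff(unique(hgvs[rest]), hgvs[setdiff(seq_len(n), rest)])
  n_ev <- cf$n_gof + cf$n_lof_missense
  if (n_ev > length(singleton)) stop("not enough missense variants for evidence",
                                     call. = FALSE)
  ev_vars <- sample(singleton, n_ev)
  evidence <- tibble::tibble(
    hgvs_p = ev_vars,
    functional = rep(c("GoF", "LoF"), c(cf$n_gof, cf$n_lof_missense))
  )

  func_of <- stats::setNames(evidence$functional, evidence$hgvs_p)
  z_mean <- ifelse(broad == "PTV", -cf$class_delta,
            ifelse(!is.na(hgvs) & hgvs %in% names(func_of) &
                     func_of[hgvs] == "GoF", cf$class_delta,
            ifelse(!is.na(hgvs) & hgvs %in% names(func_of), -cf$class_delta, 0)))
  z <- stats::rnorm(n, z_mean, 1)

  # planted association term frequencies
  if (is.null(cf$planted_or)) cf$planted_or <- 1
  odds_out <- cf$planted_freq / (1 - cf$planted_freq)
  p_out <- cf$planted_freq
  p_in <- cf$planted_or * odds_out / (1 + cf$planted_or * odds_out)

  pheno_group <- sample(c("DEE", "ASD", "BFNIS", "other_epilepsy", "atypical"),
                        n, TRUE, prob = c(255, 60, 53, 27, 18))

  # annotations --------------------------------------------------------
  base_counts <- 1L + stats::rpois(n, cf$base_lambda)
  bg_pool <- setdiff(pool, reserved)
  rec_of <- integer(n)
  for (g in seq_along(rec_members)) rec_of[match(rec_members[[g]], ids)] <- g

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    # planted (special) terms first; they count toward the individual's
    # term budget so the configured base-count median is preserved
    special <- character(0)
    if (broad[i] != "other") {
      p_pl <- if (broad[i] == "missense") p_in else p_out
      if (stats::runif(1) < p_pl) special <- planted_term
    }
    if (rec_of[i] > 0 && cf$core_p > 0) {
      core <- cores[[rec_of[i]]]
      special <- union(special,
                       core[stats::runif(length(core)) < cf$core_p])
    }
    if (cf$class_delta > 0) {
      # offset -1.5 keeps class-linked terms uncommon at z = 0 so the
      # base-term budget (median 6) is respected, while the z-dependence
      # still separates the classes strongly
      gp <- stats::plogis(z[i] - 1.5)
      lp <- stats::plogis(-z[i] - 1.5)
      special <- union(special,
                       c(gof_terms[stats::runif(length(gof_terms)) < gp],
                         lof_terms[stats::runif(length(lof_terms)) < lp]))
    }
    w <- rep(1, length(bg_pool))
    if (cf$focus_weight != 1 && length(depth1)) {
      focus <- descendant_closure(onto, sample(depth1, 1))
      w[bg_pool %in% focus] <- cf$focus_weight
    }
    k <- min(max(base_counts[i] - length(special), 1L), length(bg_pool))
    base_pos <- c(special, sample(bg_pool, k, prob = w))
    base_neg <- character(0)
    if (stats::runif(1) < cf$neg_rate) {
      prop_pos <- ancestor_closure(onto, base_pos)
      neg_pool <- setdiff(pool, prop_pos)
      if (length(neg_pool)) {
        kn <- min(min(1L + stats::rpois(1, cf$neg_lambda), 7L), length(neg_pool))
        base_neg <- sample(neg_pool, kn)
      }
    }
    rows[[i]] <- tibble::tibble(
      individual_id = ids[i],
      term = c(base_pos, base_neg),
      polarity = rep(c("positive", "negative"),
                     c(length(base_pos), length(base_neg)))
    )
  }

  list(
    annotations = dplyr::bind_rows(rows),
    variants = tibble::tibble(individual_id = ids, hgvs_p = hgvs,
                              var_class = var_class,
                              phenotype_group = pheno_group),
    evidence = evidence,
    truth = list(
      seed = cf$seed, config = cf,
      planted_term = planted_term, p_in = p_in, p_out = p_out,
      gof_terms = gof_terms, lof_terms = lof_terms,
      recurrent_members = rec_members, cores = cores,
      z = stats::setNames(z, ids),
      base_counts = stats::setNames(base_counts, ids),
      background_pool = bg_pool
    )
  )
}
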