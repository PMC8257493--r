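#' Configuration for an end-to-end pipeline run
#'
#' @param ontology Path to an OBO file.
#' @param annotations Path to the annotation TSV (see [read_annotations()]).
#' @param variants Path to the variant TSV (see [read_variants()]).
#' @param topology Optional path to a topology TSV (see [read_topology()]).
#' @param evidence Optional path to a functional-evidence TSV
#'   (`hgvs_p`, `functional`).
#' @param out_dir Output directory (created if missing).
#' @param q FDR level for association analyses (default 0.10).
#' @param n_perm Permutations per similarity test (default 100000).
#' @param k Number of logistic PCA components (default 3).
#' @param m Natural-parameter scale, or `"cv"` for cross-validated
#'   selection over `c(2, 4, 6, 8, 10)` (default 4).
#' @param seed Integer seed governing all stochastic stages (each stage
#'   draws its own sub-seed, so changing e.g. the permutation count does
#'   not perturb other stages).
#' @return A list of class `run_config`.
#' @export
run_config <- function(ontology, annotations, variants, topology = NULL,
                       evidence = NULL, out_dir = "deepheno_out",
                       q = 0.1, n_perm = 1e5, k = 3, m = 4, seed = 1L) {
  stopifnot(q > 0, q < 1, n_perm >= 1, k >= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full phenotype analysis pipeline
#'
#' Harmonizes the cohort (propagation and pruning), writes frequency and
#' information-content tables, runs variant-class and location association
#' analyses, the phenotypic-similarity suite with per-recurrent-variant
#' phenograms, and the logistic PCA with variant-function prediction.
#' All inputs are read and validated before any output is written, and a
#' machine-readable manifest (input checksums, seed, package version, file
#' list) makes identical runs verifiable.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest as a list. Side effect: TSV/JSON outputs
#'   under `config$out_dir`.
#' @export
run_all <- function(config) {
  cf <- config
  # read and validate everything up front: fail before any writes
  onto <- parse_obo(cf$ontology)
  ann <- read_annotations(cf$annotations)
  topo <- if (!is.null(cf$topology)) read_topology(cf$topology)
  vars <- read_variants(cf$variants, topology = topo)
  ev <- if (!is.null(cf$evidence)) {
    readr::read_tsv(cf$evidence, show_col_types = FALSE, comment = "#")
  }

  set.seed(cf$seed)
  stage_seeds <- sample.int(.Machine$integer.max, 4)

  dir.create(cf$out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    readr::write_tsv(df, file.path(cf$out_dir, name))
    name
  }
  files <- character(0)

  # harmonize -----------------------------------------------------------
  harmonized <- harmonize_cohort(onto, ann)
  files <- c(files, w(harmonized, "harmonized_annotations.tsv"))
  n <- dplyr::n_distinct(ann$individual_id)
  pos <- harmonized[harmonized$polarity == "positive", ]
  freq_base <- term_frequencies(pos[pos$origin == "base", ], n = n)
  freq_prop <- term_frequencies(pos, n = n)
  files <- c(files, w(freq_base, "frequencies_base_positive.tsv"),
             w(freq_prop, "frequencies_propagated_positive.tsv"))
  neg <- harmonized[harmonized$polarity == "negative", ]
  files <- c(files,
             w(term_frequencies(neg[neg$origin == "base", ], n = n),
               "frequencies_base_negative.tsv"),
             w(term_frequencies(neg, n = n), "frequencies_negative_full.tsv"),
             w(term_frequencies(neg[neg$in_pruned, ], n = n),
               "frequencies_negative_pruned.tsv"))
  shift <- compare_term_frequencies(freq_base, freq_prop, n = n, q = cf$q)
  files <- c(files, w(shift, "propagation_frequency_shift.tsv"))

  # association ---------------------------------------------------------
  everyone <- sort(union(unique(ann$individual_id), vars$individual_id))
  mat <- phen_matrix(harmonized, individuals = everyone)
  vc <- vars[vars$broad_class != "other", ]
  assoc <- associate(mat[vc$individual_id, , drop = FALSE],
                     vc$broad_class == "missense", q = cf$q,
                     analysis = "missense_vs_PTV")
  files <- c(files, w(assoc, "association_variant_class.tsv"))
  loc_assoc <- NULL
  if (!is.null(topo)) {
    loc_assoc <- location_associations(vars, mat, q = cf$q)
    files <- c(files, w(loc_assoc, "association_location.tsv"))
  }

  # similarity ----------------------------------------------------------
  freqs <- term_frequencies(pos, n = n)
  sim <- similarity_matrix(harmonized, onto, freqs)
  suite <- run_similarity_suite(sim, vars, n_perm = cf$n_perm,
                                seed = stage_seeds[1])
  files <- c(files, w(suite, "similarity_suite.tsv"))
  rec <- suite[suite$family == "recurrent_variant" & suite$n >= 5, ]
  for (lab in rec$group) {
    g <- vars$individual_id[!is.na(vars$hgvs_p) & vars$hgvs_p == lab]
    g <- intersect(g, unique(harmonized$individual_id))
    ph <- phenogram(harmonized, g)
    files <- c(files, w(ph, paste0("phenogram_", gsub("[^A-Za-z0-9]", "_", lab),
                                   ".tsv")))
  }

  # reduction -----------------------------------------------------------
  X <- phen_matrix(harmonized, polarity = "positive", individuals = everyone)
  m_use <- if (identical(cf$m, "cv")) {
    attr(cv_logistic_pca(X, k = cf$k, seed = stage_seeds[2]), "best_m")
  } else cf$m
  fit <- fit_logistic_pca(X, k = cf$k, m = m_use)
  files <- c(files, w(tidy(fit, "scores"), "pca_scores.tsv"),
             w(tidy(fit, "loadings"), "pca_loadings.tsv"),
             w(tidy(fit, "deviance"), "pca_scree.tsv"))
  pred <- NULL
  if (!is.null(ev)) {
    fv <- assign_function(vars, ev)
    if (any(fv$functional == "GoF") && any(fv$functional == "LoF")) {
      pred <- predict_variant_function(fv, fit)
      files <- c(files, w(pred, "predicted_variant_function.tsv"))
      eval_json <- glance(attr(pred, "eval"))
      eval_json$component <- attr(pred, "component")
      jsonlite::write_json(as.list(eval_json),
                           file.path(cf$out_dir, "classifier_eval.json"),
                           auto_unbox = TRUE, digits = NA)
      files <- c(files, "classifier_eval.json")
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("deepheno")),
    seed = cf$seed,
    parameters = list(q = cf$q, n_perm = cf$n_perm, k = cf$k, m = m_use),
    inputs = lapply(
      Filter(Negate(is.null),
             list(ontology = cf$ontology, annotations = cf$annotations,
                  variants = cf$variants, topology = cf$topology,
                  evidence = cf$evidence)),
      function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(stats::setNames(files, files), function(f) {
      unname(tools::md5sum(file.path(cf$out_dir, f)))
    }),
    summary = list(
      n_individuals = n,
      n_base_positive = sum(pos$origin == "base"),
      n_propagated_positive = nrow(pos),
      n_unique_propagated = dplyr::n_distinct(pos$term),
      n_significant_class_terms = sum(assoc$significant),
      n_significant_location_terms =
        if (is.null(loc_assoc)) NA else sum(loc_assoc$significant)
    )
  )
  jsonlite::write_json(manifest, file.path(cf$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
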