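#!/usr/bin/env Rscript

# Thin command-line wrapper over deepheno::run_all(): harmonize a cohort,
# run association, similarity and reduction analyses, and write all result
# tables plus a manifest to an output directory.

suppressMessages({
  library(optparse)
  library(deepheno)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--ontology", type = "character", help = "OBO file"),
  make_option("--annotations", type = "character",
              help = "TSV: individual_id, term (NP: prefix for negatives)"),
  make_option("--variants", type = "character",
              help = "TSV: individual_id, hgvs_p, var_class, phenotype_group"),
  make_option("--topology", type = "character", default = NULL,
              help = "TSV: region, segment, start, end [optional]"),
  make_option("--evidence", type = "character", default = NULL,
              help = "TSV: hgvs_p, functional (GoF/LoF/mixed) [optional]"),
  make_option("--out", type = "character", default = "deepheno_out"),
  make_option("--q", type = "double", default = 0.1, help = "FDR level"),
  make_option("--n-perm", type = "integer", default = 100000,
              dest = "n_perm", help = "similarity permutations"),
  make_option("--k", type = "integer", default = 3, help = "PCA components"),
  make_option("--m", type = "character", default = "4",
              help = "natural-parameter scale, or 'cv'"),
  make_option("--seed", type = "integer", default = 1L)
)))

for (req in c("ontology", "annotations", "variants")) {
  if (is.null(opts[[req]])) stop("--", req, " is required", call. = FALSE)
}

cfg <- run_config(
  ontology = opts$ontology, annotations = opts$annotations,
  variants = opts$variants, topology = opts$topology,
  evidence = opts$evidence, out_dir = opts$out,
  q = opts$q, n_perm = opts$n_perm, k = opts$k,
  m = if (opts$m == "cv") "cv" else as.numeric(opts$m),
  seed = opts$seed
)
manifest <- run_all(cfg)
cat("outputs written to", opts$out, "-",
    length(manifest$outputs), "files\n")
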