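# deepheno

Quantitative deep-phenotyping of patient cohorts annotated with Human
Phenotype Ontology (HPO) terms — including explicitly asserted *absent*
("negative") phenotypes — with genotype–phenotype association testing,
permutation-based phenotypic similarity, and logistic PCA for variant
function prediction.

The package was built for cohorts like the *SCN2A*-related disorders, where
clinical reports of varying depth are harmonized into HPO terms and
correlated with variant classes (missense vs protein-truncating), variant
locations within an ion channel (here the Na_V_1.2 α-subunit), and
electrophysiological consequences (gain- vs loss-of-function, GoF/LoF). It
is written for statistical geneticists and clinical informaticians working
with tabular per-individual annotation, variant and topology data.

## What it computes

**Harmonization.** Directly assigned ("base") positive terms are expanded
upward with every ancestor ("propagated" terms); for a term *t* with cohort
frequency *f(t)*, the information content is

    IC(t) = -log2 f(t)   [bits]

so rarer terms are more informative. Negative assertions propagate
*downward* (absence of a phenotype implies absence of its subtypes),
blocked wherever that would contradict a positive annotation, and are then
pruned to the apex of each negative region — a lossless compression
(re-propagating the pruned set restores the full set exactly).

**Association.** Each propagated term (positive and pruned-negative
columns) is tested against a binary grouping — variant class, or missense
location in the channel topology — with a two-sided Fisher exact test
(conditional-MLE odds ratio, exact 95% CI) and Benjamini–Hochberg control
at FDR 10%.

**Similarity.** The similarity of two terms is the IC of their most
informative common ancestor (MICA); the similarity of two individuals is
the best-match average over their propagated positive term sets,

    sim(A, B) = ( Σ_{a∈A} max_{b∈B} IC(MICA(a,b))
                + Σ_{b∈B} max_{a∈A} IC(MICA(a,b)) ) / 2.

A subgroup's cohesion is the median of its pairwise similarities, tested
against a null built by drawing equally many individuals from the whole
cohort (default 100,000 permutations), with the add-one p-value
`p = (1 + #{null ≥ observed}) / (N + 1)`.

**Reduction.** Logistic PCA factorizes the binary individuals × terms
matrix by minimizing the Bernoulli deviance of rank-k projected natural
parameters Θ = 1μ′ + (m(2X−1) − 1μ′)UU′, fitted by
majorization–minimization. Component scores are evaluated against
phenotype groups and GoF/LoF labels via ROC/AUC, Youden cutoffs,
precision–recall/F1 and empirical PPV curves, and used to classify
variants of unmeasured function.

**Synthetic cohorts.** `generate_ontology()` and `generate_cohort()`
produce seeded cohorts with known planted effects (class-linked term odds
ratios, recurrent-variant groups with shared term cores, a GoF/LoF latent
factor), so every stage can be validated against ground truth without any
download.

## Worked example

A two-patient toy cohort on the bundled 30-term mini ontology:

```r
library(deepheno)
library(tibble)

onto <- parse_obo(mini_hpo_path())
ann <- tribble(
  ~individual_id, ~term,         ~polarity,
  "P1", "HP:0012469", "positive",   # infantile spasms
  "P1", "HP:0002521", "positive",   # hypsarrhythmia
  "P1", "HP:0012443", "negative",   # no structural brain abnormality
  "P2", "HP:0000717", "positive",   # autism
  "P2", "HP:0001250", "negative"    # no seizures
)
h <- harmonize_cohort(onto, ann)
dplyr::count(h, individual_id, polarity, origin)
#> # A tibble: 8 × 4
#>   individual_id polarity origin         n
#> 1 P1            negative base           1
#> 2 P1            negative propagated     2
#> 3 P1            positive base           2
#> 4 P1            positive propagated     7
#> 5 P2            negative base           1
#> 6 P2            negative propagated     6
#> 7 P2            positive base           1
#> 8 P2            positive propagated     5
```

P1's two base terms expand to nine positive terms; the negative "no
structural brain abnormality" propagates down to its two subtypes, and
P2's "no seizures" expands to six absent seizure subtypes (never
contradicting the positive autism annotation).

```r
fr <- term_frequencies(h[h$polarity == "positive", ], n = 2)
mica(onto, fr, "HP:0012469", "HP:0002133")
#> $term
#> [1] "HP:0001250"
#> $ic
#> [1] 1
```

Infantile spasms and status epilepticus meet at "Seizures", carried by one
of the two individuals, hence IC = −log2(1/2) = 1 bit. Individual-level
similarity follows the same logic: here `individual_similarity()` gives
`sim(P1, P1) = 5` (the IC sum of P1's informative terms) and
`sim(P1, P2) = 0` — the two patients share only IC-0 ancestors, so their
phenotypes carry no common information.

At cohort scale the same calls chain into `associate()`,
`group_similarity_test()`, `phenogram()`, `fit_logistic_pca()` and
`predict_variant_function()`; `run_all()` orchestrates the full pipeline
from TSV inputs to a manifest-stamped output directory, and
`scripts/run_pipeline.R` wraps it for the shell. See the methods vignette
(`vignettes/deep-phenotyping.Rmd`) for the statistical details and design
choices.

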