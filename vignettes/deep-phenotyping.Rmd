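---
title: "Methods: ontology-based deep phenotyping with deepheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ontology-based deep phenotyping with deepheno}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepheno)
```

deepheno analyzes cohorts of individuals annotated with Human Phenotype
Ontology (HPO) terms, including explicitly asserted absent phenotypes. This
vignette documents the statistical model behind each stage, the parameters
that matter, the design decisions that were genuinely open, and what the
synthetic-data validation does and does not demonstrate about real data.

## The annotation model

An HPO-style ontology is a rooted directed acyclic graph of terms linked by
`is_a` edges. An individual's record consists of *base positive* terms
(phenotypes observed and recorded) and *base negative* terms (phenotypes
whose absence was explicitly documented). Two asymmetric inference rules
harmonize records of different depth:

* **Positive terms propagate upward.** Observing "Infantile spasms" entails
  "Epileptic spasms", "Seizures", and so on up to the root. `propagate_positive()`
  is the ancestor closure of the base set and is idempotent.
* **Negative terms propagate downward.** "No seizures" entails the absence
  of every seizure subtype. Downward propagation is blocked at any node
  that is positively annotated or subsumes a positive annotation: positive
  observations dominate. A base negative that is *directly* asserted
  positive as well is a curation conflict and raises an error; conflicts
  arising only through propagation are silently resolved in favor of the
  positive, because they are an unavoidable consequence of the closure
  (any negative whose descendant is positive would otherwise be
  unreachable).

Absence of a term from a record means *not recorded*, never *absent*;
only asserted negatives are treated as absence.

Downward propagation over a large ontology produces many redundant
negatives, so `prune_negative()` keeps only the apex of each negative
region (terms with no negative parent). The compression is lossless:
re-running downward propagation from the apexes restores the full set
exactly, a property the test suite checks on random DAGs.

The information content of a term with cohort frequency $f$ is
$\mathrm{IC} = -\log_2 f$ bits. After propagation, $f(\text{parent}) \ge
f(\text{child})$ along every edge, so IC is monotone non-increasing toward
the root; the root always has IC 0. In a cohort of 413 individuals a
singleton term attains the maximum $-\log_2(1/413) \approx 8.69$ bits.

## Association testing

Each term column (positive `HP:` and pruned-negative `NP:` columns) is
cross-tabulated against a binary grouping and tested with a two-sided
Fisher exact test. We report the conditional maximum-likelihood odds ratio
with its exact 95% confidence interval (zero cells yield 0 or `Inf` point
estimates with one finite bound) and, for transparency, the sample odds
ratio $ad/bc$. Multiple testing is controlled by Benjamini–Hochberg at
FDR $q = 0.10$ (the package default), with one correction per named
analysis: one family for the variant-class analysis, and one pooled family
across all locations $\times$ terms for the location analysis. Whether
positive and negative terms should form separate families is debatable; we
pool them (they answer one question per analysis) and additionally report
per-location flags so either reading is recoverable from the output.
Propagated term columns are strongly positively dependent (each implies
its ancestors), which BH tolerates; the null-calibration test verifies
that the chance of any rejection on an effect-free cohort stays near
nominal.

## Phenotypic similarity

Term-pair similarity is Resnik's measure: the IC of the most informative
common ancestor (MICA), with each term counted among its own ancestors so
a term subsuming another is a valid (often the maximal) common ancestor.
MICA ties are broken by the lexicographically smallest term id, which is
deterministic and never changes the IC. Frequencies always come from the
*propagated* dataset; a common ancestor missing from the frequency table
is a hard error rather than an imputation, because a partial table would
silently bias scores.

Individual-pair similarity is the best-match sum in both directions,
symmetrized by the arithmetic mean. The source sentence for this statistic
is ambiguous between a one-directional sum, a symmetric sum, and their
mean; we chose the mean so that self-similarity is on the same scale for
small and large term sets, and expose `symmetrize = "sum"` for the
alternative. Only positive propagated terms enter the score; negative
assertions carry different semantics (certified absence) and are excluded.

A subgroup's observed statistic is the **median of its pairwise
similarities** (the other defensible reading — median of per-individual
best scores — is not implemented). The null distribution draws the same
number of individuals uniformly *without* replacement from the entire
cohort, including the subgroup's own members, and the p-value uses the
add-one formula $p = (1 + \#\{\text{null} \ge \text{obs}\})/(N+1)$, which
is never zero and bounded below by $1/(N+1)$. Individuals with empty
propagated sets score 0 with a warning and should be excluded from group
tests by the caller; the suite runner drops groups below two members.

`run_similarity_suite()` tests broad variant classes, each channel domain,
each segment class pooled across domains, missense carriers excluding the
S5–S6 pore loop, and every recurrent variant with at least two carriers.
Each group gets an independent sub-seed derived from the suite seed, so
adding or removing one group does not perturb the others.

## Logistic PCA and variant-function prediction

The binary individuals × terms matrix $X$ is factorized by logistic PCA:
natural parameters are modeled as
$\Theta = \mathbf{1}\mu' + (\tilde\Theta - \mathbf{1}\mu')UU'$ with
$\tilde\Theta = m(2X - 1)$, $U$ column-orthonormal, and the Bernoulli
deviance of $\Theta$ minimized by majorization–minimization: the logistic
loss is majorized by a quadratic with curvature $1/4$, giving closed-form
updates ($\mu$ from column means of the working response, $U$ from the
top-$k$ eigenvectors of a working cross-product matrix). Initialization is
the SVD of the centered $\tilde\Theta$, so the fit is deterministic;
non-convergence at `max_iter` flags the result instead of failing.

Parameters that matter:

* `m` (dimensionless): the cap on saturated natural parameters.
  Default 4 (a fitted probability cap of $\sigma(4) \approx 0.982$);
  `cv_logistic_pca()` offers 5-fold cross-validated selection over
  $\{2, 4, 6, 8, 10\}$ by held-out deviance.
* `k`: number of components, default 3, matching the number of broad
  clinical groups such a cohort is expected to stratify into.
* `min_count`: columns with fewer than 2 carriers are excluded — a private
  term carries no shared signal and only adds noise to the loadings.

Deviance explained is reported per component against the intercept-only
(column-frequency) model, using the nested profile of the leading
components of a single fit. Each component is oriented so that its score
correlates positively with the presence of its top-loading term; a global
sign flip of a loading column with its scores leaves the fit invariant, so
orientation is a reporting convention, not a model choice.

`evaluate_component()` computes the AUC by the midrank statistic (exactly
the pairwise concordance probability, tie-corrected), the Youden-optimal
cutoff with ties resolved toward sensitivity, precision–recall and F1 at
that cutoff, and empirical PPV/NPV sweeps. `predict_variant_function()`
re-orients the chosen component so higher scores mean gain-of-function,
thresholds at the Youden cutoff estimated from the functionally labeled
subset, and reads each individual's PPV off the labeled empirical curve
(for a GoF call: the fraction of GoF among labeled individuals scoring at
least as high). Protein-truncating variants are labeled loss-of-function
unconditionally; variants with mixed electrophysiology are excluded. A
recurrent variant is scored once per carrier, so phenotypically divergent
carriers can legitimately receive different calls.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure of a
literature-curated ion-channel cohort. Its defaults are the study
conditions used throughout validation and were fixed before the validation
suite was run:

* 413 individuals split 341 missense / 68 PTV / 4 other;
* base positive counts $1 + \mathrm{Poisson}(5)$ targeting a median of 6
  terms per individual, sampled with a per-individual "focus subtree" bias
  (weight 4) that creates realistic co-occurrence;
* negative assertions in $260/413 \approx 63\%$ of individuals, 1–7 terms
  with median 2, drawn only from terms outside the individual's positive
  closure (mirroring the curation rule that absence must not contradict an
  observation);
* one term planted at odds ratio 8 between missense and PTV carriers at
  out-group frequency 0.15;
* recurrent-variant groups of sizes (18, 14, 10, 5, 5, 3, 3, 2, 2), each
  sharing a 4-term core carried with probability 0.8;
* a latent GoF/LoF factor $z$ with class means $\pm 1.5$ SD expressed
  through 6 GoF-linked and 6 LoF-linked terms with inclusion probability
  $\sigma(\pm z - 1.5)$ — uncommon at $z = 0$ so the base-count budget is
  respected, strongly class-dependent so the phenotype carries the
  class signal. The $\pm 1.5$ separation was chosen once as a plausibly
  strong electrophysiology–phenotype coupling.

Planted terms are drawn from ontology *leaves* so that carrier status
after propagation equals the planted Bernoulli draw exactly; an internal
term would also be reached from background descendants and the realized
odds ratio would no longer be the configured one. Planted ("special")
terms count toward the individual's term budget, preserving the configured
median.

The truth record carries every planted effect, the per-individual budgets
and the background pool; in the no-effect configuration with uniform
sampling, expected term frequencies are analytic
($c_i/|\text{pool}|$ per individual) and the tests verify the empirical
counts against them.

**What passing tests show — and what they do not.** The generator
reproduces the *dependence structure* the pipeline must handle (nested
propagated columns, group-linked terms, clone-like subgroups, a latent
class factor), so green tests demonstrate correctness of the algorithms
and calibration of the statistics under that structure. They do not
demonstrate that real clinical cohorts satisfy the generator's
simplifications: real HPO co-occurrence is richer than one focus subtree,
real negative assertions are rarer and more systematic, and real
effect sizes are not known in advance. Results on real data inherit the
usual caveats of literature curation.

## Numerical choices and degenerate inputs

* Fisher p-values are clamped at 1 (the exact-summation implementation can
  overshoot by one ulp); BH flags are order-invariant.
* `fisher_2x2` with a zero margin still returns a valid test; an all-zero
  2×2 table is an error.
* MM iterations stop when the relative deviance change falls below `tol`
  ($10^{-6}$ by default, dimensionless); the deviance is computed with
  `log1p(exp(·))` for stability.
* Empty annotation sets similarity-score 0 with a warning; groups of one
  are skipped; a group equal to the whole cohort is rejected (its
  permutation null would be degenerate).
* Cohort-scale problem sizes in the validation suite were chosen to make
  every check exhaustive-oracle-verifiable: random DAGs up to 50 nodes
  against boolean matrix-power closure, 100 term-set pairs against a
  double-loop MICA search, 500 permutation tests of size-5 groups at
  2,000 permutations on a 150-individual null cohort, 100 planted-effect
  and 200 null association replicates, and rank-1 logistic PCA recovery at
  $n = 200, p = 50$.

## Limitations

* Only `is_a` relations are interpreted; `part_of` and cross-ontology
  logical definitions are out of scope.
* The channel topology bundled with the package is a synthetic
  best-effort reconstruction with plausible interval boundaries;
  boundary-sensitive location results should be treated as approximate and
  a curated topology substituted when available.
* Exact tests only: no covariate adjustment (ascertainment, publication
  era, assay differences) is attempted.
* The term-pair kernel of the similarity module is pluggable in principle
  (alternative similarity measures are an extension point), but only the
  Resnik/MICA kernel ships.
* Prediction of variant function is a ranking with empirical PPV, not a
  calibrated probability.
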