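---
title: "Missense functionality profiling: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Missense functionality profiling: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(missprof)
```

## The problem

For a handful of intensively studied genes — *TP53* foremost — the functional
impact of a missense variant can be read out directly: yeast transactivation
assays, mammalian cell-cycle-arrest screens and phenotype screens
(dominant-negative activity, loss of function, drug response) together score
essentially the whole substitution space. missprof turns such scores into a
gene-specific classifier of *functionality* — "functionally abnormal"
(deleterious, D) versus "functionally normal" (non-deleterious, ND) — for
every possible missense variant of a coding sequence, and validates the
predictions against annotation databases, familial-cancer cohorts,
population frequency tables and survival-stratified tumor cohorts.

The pipeline is deliberately split into small, separately testable stages:

1. **Variant space** (`enumerate_snvs`). A CDS of length $L$ nucleotides
   admits exactly $3L$ single-nucleotide substitutions; each is translated
   in place and classified (synonymous / missense / nonsense / stop_loss /
   stop_retained), and missense events are deduplicated to protein variants
   on (reference amino acid, codon, alternate amino acid). A 394-codon ORF
   therefore yields $3 \times 1182 = 3546$ events.
2. **Labels from prevalence** (`build_positive_set`, `build_negative_set`).
   The positive class is the *cancer-shared dataset* (CSD): variants
   observed at least once in **every one** of several independent cancer
   mutation databases. The negative class exploits mutational saturation:
   variants never observed, or observed only once, across the aggregate
   corpus.
3. **Features** (`feature_matrix`, `impute_median`). A variants × 42-score
   table in two groups — 14 functional-assay readouts and 28 computational
   predictor scores — with per-feature median imputation.
4. **Classifier** (`prof_fit` and the protocol helpers). Gradient boosting
   (xgboost) and random forests (ranger) under a 60:20:20 protocol.
5. **Validation harnesses** and **prevalence statistics** (GVS ratio, MMF).
6. **Synthetic generators** for every input, so the whole pipeline runs and
   is tested without any external download.

## The training protocol

`split_data` partitions the labeled cohort 60:20:20 by the floor rule:
validation and test each receive $\lfloor 0.2n \rfloor$ variants and the
remainder trains. A cohort of 1294 labeled variants splits 778/258/258.
Splits are stratified by label by default — the deleterious class is several
times smaller than the negative class, and stratification keeps its share
equal across partitions (unstratified splits are available with
`split_spec(stratified = FALSE)`).

`prof_fit` tunes by **random search**: `n_candidates` configurations drawn
from the search space, each scored by mean stratified 10-fold
cross-validated AUC on the training partition, best refit on the full
partition. The default GBM space is tree depth 2–8, learning rate 0.01–0.3
(log-uniform), 100–1000 rounds, row subsampling 0.5–1.0; the RF space is
mtry 1–p and minimum node size 1–10 at 500 trees. These spaces are package
defaults, not estimates of anything; `n_candidates` defaults to 50.

`compare_models` repeats tuned runs (default 10) per (algorithm, feature
set) candidate and averages validation AUC and accuracy; `select_model`
takes the argmax of mean AUC with ties broken by mean accuracy and then by
algorithm order (GBM first — a fixed, documented tie-break, not a
preference learned from data). `finalize_and_test` refits the winner on
train + validation (80%) with the same tuning procedure and evaluates
exactly once on the sealed test partition.

The decision threshold on the predicted probability of D defaults to 0.5,
with the boundary convention that a probability exactly at the threshold is
called D. AUC is the rank (Mann–Whitney) statistic with mid-rank ties, so it
is invariant under monotone transforms of the probabilities; accuracy
additionally depends on the threshold, which is why both are reported.

## What the generators emulate

`simulate_cohort` is not a toy: its defaults *are* the study conditions the
package is tested under, chosen once on domain grounds.

* **Scales.** 2314 missense variants, a 290-variant planted CSD, 693 + 323
  absent/singleton negatives in four databases — the accounting of a
  saturated tumor-suppressor mutation corpus, so set-recovery tests read
  naturally.
* **Functional scores** are strongly bimodal in the latent functionality
  class: class means 4 within-class standard deviations apart. Real
  transactivation and screen readouts separate functional from
  non-functional variants nearly completely (cross-validated AUCs in the
  high 0.99s), and 4 sd reproduces that regime without being degenerate.
* **Computational scores** carry the same signal at 1.5 sd — individually
  informative but far from clean, matching the well-documented gap between
  in-silico predictors and direct assays.
* **Partial-function variants.** 7% of variants draw *all* their scores
  from a distribution centred midway between the two modes. This emulates
  the known hard cases — splice-affecting substitutions assayed from
  forced cDNA expression, oligomerization-domain variants that score
  active under overexpression, genuinely partial loss of function — which
  are the dominant error source for assay-based classifiers. A classifier
  with a mid-range threshold calls about half of them each way, so the
  expected ceiling on test accuracy is roughly $1 - 0.07/2 \approx 96.5\%$,
  the regime this class of model operates in on real data.
* **Domain-restricted missingness.** The cell-cycle-arrest readout is only
  observed for variants in codons 94–312 (the DNA-binding domain in the
  real assay); all other scores go missing at random at 5%.
* **Tumor corpora** are 91% single-, 7% double- and 2% multi-variant
  (multi = 3 + Poisson(0.5)), the composition reported for large curated
  corpora; germline records default to 10% of the corpus.
* **Survival cohorts** draw exponential event times scaled by per-category
  hazard ratios with independent exponential censoring. The default
  category mix mirrors a pan-cancer somatic cohort (missense-ND tumors are
  rare, ~1%); hazard-ratio *recovery* tests use a balanced mix instead,
  because no estimator recovers an HR to ±15% from a 1% stratum, and that
  is a property of the data, not of the implementation.

What the generators do **not** emulate: the empirical (non-Gaussian) score
distributions of the real mutagenesis screens, correlated missingness
across predictors, hotspot-specific mutational processes, or
tumor-type-specific baseline hazards. Passing tests therefore demonstrate
that the machinery is correct and well calibrated under realistic
separation, noise and missingness — not that any particular real-data
accuracy is guaranteed.

## Numerical and policy choices

* **Initiator codon.** Non-synonymous changes in codon 1 count as missense
  protein variants (flagged `start_codon`); the convention is configurable
  (`count_start_codon = FALSE` reclassifies them `start_lost`). Stop-codon
  events are `stop_loss`/`stop_retained` and never enter the missense
  space. These conventions make the protein-variant accounting of a
  393-residue protein reach its full 2314-variant missense space.
* **Negative-set rule.** "Never or once observed" is applied to the total
  count summed over all supplied databases (threshold and summation rule
  are arguments); occurrences of distinct cDNA events producing one
  protein variant are summed before thresholding.
* **Imputation scope.** Medians are computed over the whole table by
  default (`fit_on = "all"`), matching how assay tables are distributed;
  `fit_on = <training keys>` restricts them to the training partition for
  a leakage-free variant of the protocol. Median of an even count is the
  mean of the middle two. A feature with no observed value in the fit
  subset is a hard error, never silently zero-filled.
* **MDS.** Classical (Torgerson) scaling of the Euclidean distance matrix
  via eigendecomposition — deterministic up to axis sign; degenerate
  configurations spanning fewer than two dimensions are zero-padded.
* **Zero denominators** in confusion statistics yield `NA` ("undefined"),
  never 0; percentages are kept at full precision with rounded convenience
  fields at 2 decimals.
* **GVS ratio.** No canonical formula exists for the germline-to-somatic
  ratio; the package defines it as the ratio of pseudocount-smoothed
  relative record frequencies, $\frac{(g_v+a)/(G+a)}{(s_v+a)/(S+a)}$ with
  $a = 0.5$ by default. With $a = 0$ it is exactly antisymmetric under
  compartment swap. This is an interpretation, documented as such.
* **Annotation curation order.** Conflicting or absent labels collapse to
  a single VUS record *before* duplicate accounting, so only same-tier
  copies count as duplicates (a 778-record table with 22 same-tier
  duplicates and 8 indel-derived records retains 748). The operation is
  idempotent.
* **Survival comparisons** use the score test from a two-group Cox
  proportional-hazards fit (not the log-rank statistic), and the
  multivariable fit runs on missense samples with tumor type as a factor
  covariate after removing configured outlier tumor types (default PCPG,
  TGCT, DLBC). Samples with multiple mutations, patients with multiple
  samples, and non-missense non-truncating mutation classes are excluded
  with per-reason accounting.

## Problem sizes in the test suite

The suite exercises the full pipeline at its natural scale — 2314-variant
universes, 1294-variant labeled cohorts with 778/258/258 splits — and uses
reduced tuning budgets (3–10 random candidates, 3–10 folds) where the
tuning *protocol* rather than the tuned optimum is under test. Property
suites run 100 random ORFs against a re-translation oracle, 1000 random AUC
instances against a pairwise oracle, 1000 null survival replicates for
type-I calibration, and 5-seed parameter-recovery runs; everything is
seeded and deterministic.

## Known limitations

* Only substitution HGVS grammar is parsed; indel/splice/intronic notation
  is deliberately routed to an "unsupported" marker for curation
  accounting, not interpreted.
* Scores are consumed, never computed: the package has no opinion about
  how SIFT, EVE, CHASM or a transactivation assay produced its numbers
  beyond the direction metadata in the feature spec.
* The classifier is gene-specific by construction; nothing transfers
  across genes except the machinery.
* Tree ensembles are scale-invariant, so features are used untransformed;
  if you add a model family that is not, standardize first.
* A probability from `prof_fit` is a classifier score, not a calibrated
  posterior; threshold it, or calibrate downstream if you need
  probabilities.
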