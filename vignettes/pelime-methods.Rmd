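---
title: "Methods: from plasma proteomics to pulmonary-embolism genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from plasma proteomics to pulmonary-embolism genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pulmonary embolism (PE) and deep vein thrombosis (DVT) are the two faces
of venous thromboembolism (VTE). Why a thrombus embolizes to the lung in
some patients and stays in the leg in others is largely unexplained.
`pelime` implements a discovery pipeline for this question: learn to
separate isolated PE from isolated DVT using plasma protein profiles
(antibody suspension-bead-array intensities plus routine biological
traits), distil the classifier into a per-subject quantitative risk
score, and then ask genetics which variants move that score and the PE
phenotype itself.

The pipeline is exercised end-to-end on a seeded synthetic cohort
generator, so every stage is testable without patient-level data.

## Pipeline and model

1. **Standardization** (`fit_standardizer`, `apply_standardizer`). Every
   feature is scaled to zero mean and unit variance. We use the
   population (divide-by-$n$) variance convention; either convention
   satisfies the mean-0/variance-1 contract, so the choice is documented
   and fixed rather than important. Constant features cannot be scaled;
   they are mapped to all-zeros instead of dropped so the classifier's
   input width (395 by default) is preserved.
2. **ENN homogenization** (`enn_filter`). The mixed DVT+PE class is
   discarded by the caller; the DVT majority is then under-sampled by
   edited nearest neighbours: a DVT subject is removed iff the simple
   majority of its $k = 3$ nearest neighbours (Euclidean distance on the
   standardized feature vector) carries the other label. Minority (PE)
   subjects are never removed. The vote is the standard Wilson editing
   rule; distance ties are broken by ascending subject index so the
   filter is deterministic and permutation-equivariant.
3. **Iterative balanced training** (`balanced_iteration_sample`,
   `adasyn_generate`, `iterative_train`). Each iteration draws 30 real
   PE and 100 real DVT subjects without replacement and adds 70
   ADASYN-synthetic PE points, giving a balanced 100 vs 100 set. ADASYN
   allocates synthetic points to minority subjects in proportion to the
   fraction of majority points among their $k = 5$ pooled nearest
   neighbours (the algorithm's canonical default; the neighbourhood
   size is not dictated by the study design), with largest-remainder
   rounding so exactly `g_total` points are produced; each synthetic
   point is a convex combination of a minority point and one of its
   minority neighbours. Difficulty weights are computed on the
   per-iteration 130-subject subsample, not the full pool, matching the
   sampling-then-augmenting order of the design. If no minority point
   borders the majority the allocation falls back to uniform.
4. **The classifier** (`init_network`, `sgd_fit`). A feed-forward
   network $395 \to 395 \to 128 \to 2$ with ReLU hidden activations and
   a max-shift-stabilized softmax output, trained by plain mini-batch
   SGD (learning rate 0.01, batch 32) on the mean cross-entropy, with a
   seeded 90/10 inner split and early stopping on the inner-validation
   loss (the best snapshot is kept; training stops after `patience`
   non-improving epochs). Weights are He-initialized (fan-in scaled,
   the standard choice for ReLU); biases start at zero. No momentum or
   adaptive step sizes: the recipe is deliberately plain gradient
   descent. Weights persist across iterations (warm start) — without
   persistence only the last iteration's set would matter — and a fixed
   monitoring split (10% of the pool, stratified) selects the
   best-of-run snapshot with its own iteration-level patience.
5. **LIME** (`explain_instance`, `cohort_predictor`). For each subject,
   5000 perturbations are drawn feature-wise from the training
   distribution ($\mathcal N(\mu_i, \sigma_i)$ per feature, the
   standard tabular construction), weighted by proximity
   $w_j = \exp(-d_j^2 / \sigma_k^2)$ with kernel width
   $\sigma_k = 0.75\sqrt{p}$, and a ridge-stabilized weighted linear
   surrogate of the network's PE probability is fitted. The surrogate
   evaluated at the subject itself, clipped to $[0,1]$, is the
   subject's *local prediction*. **Key interpretive decision:** the
   cohort-wide quantitative "LIME predictor" is defined as each
   subject's own local prediction — the per-individual "local
   prediction" column generalized to everyone. A single global
   surrogate would also be defensible; the per-subject definition is
   the default because it preserves the local character of the method.
   Global feature importance is the mean absolute local weight across
   subjects (the aggregation is not dictated; mean absolute weight is
   the obvious symmetric choice).
6. **Genetics** (`quant_scan`, `trend_test`, `fisher_recessive`,
   `logistic_recessive`). The predictor is treated as a quantitative
   trait: per SNP passing the imputation-quality ($r^2 > 0.5$) and
   frequency (MAF $> 0.01$) filters, a simple linear regression of the
   predictor on effect-allele dosage (no covariates — the scan design
   names none; hooks exist but default off), flagged genome-wide
   significant at $p < 5 \times 10^{-8}$. Case-control genetics of a
   candidate SNP uses *best-guess* genotypes (nearest integer, halves
   rounding up — ties have measure zero in imputed dosages):
   Cochran-Armitage trend ($N r^2$ form, $\chi^2_1$), the exact
   recessive test (AA vs GG+GA; two-sided $p$ = sum of hypergeometric
   probabilities no larger than the observed table's, the common
   convention), and logistic regression adjusted for age and sex,
   fitted by IRLS in the package. A zero AA cell among cases or
   controls is complete/quasi-separation: the odds ratio is reported
   as *undefined*, never as a diverged number.
7. **Rare variants** (`prioritize_variants`). Tier 1: likely functional
   (stop gain/loss, frameshift, non-synonymous, splicing), in a curated
   VTE gene panel, unreported or below 1‰ in population repositories,
   and singleton among the sequenced patients. Tier 2 (only when tier 1
   is empty) drops the gene restriction but requires deleteriousness
   support: scaled CADD ≥ 20, or SIFT ≤ 0.05 together with PolyPhen ≥
   0.85. The source tools are named in the design but not their
   cutoffs; these defaults are conventional and configurable. An absent
   population frequency passes the rarity filter ("not reported" is
   evidence of rarity, not of commonness).

## The synthetic cohort generator

`generate_cohort` emulates what the analysis assumes about the real
data, with defaults set to the study conditions:

* class sizes 1105 DVT / 95 PE / 188 DVT+PE; age and sex marginals per
  class (mean ages about 47-52, 65-82% female);
* 376 antibody + 19 biotrait intensities, log-normal (the distribution
  family of MFI readouts is not documented anywhere we can rely on;
  log-normal is an explicit assumption), with block-correlated log-scale
  noise (blocks of 10, correlation 0.5) standing in for antibodies that
  target overlapping proteins;
* 20 informative antibodies shifted by `effect_size_sd_units` log-scale
  standard deviations in PE (half-shift in DVT+PE, an intermediate
  phenotype), default 0.5 — a moderate signal; the strongly planted
  acceptance scenario uses 1.5;
* 2 interaction pairs that receive, in PE only, a shared random-sign
  displacement: the pair's co-movement changes while the marginal means
  stay put, so part of the signal is invisible to any purely linear
  margin test;
* `generate_genotypes`: independent SNPs in Hardy-Weinberg proportions
  (allele frequencies uniform on 0.05-0.5), dosages = allele counts plus
  imputation noise growing as $r^2$ falls, $r^2 \sim U(0.3, 1)$ so
  roughly a quarter of SNPs fail the 0.5 filter; one causal SNP
  (effect-allele frequency 0.09, liability log-odds ln 5.3 for
  homozygotes) drawn *conditional on class* by reweighting the
  Hardy-Weinberg prior with the class likelihood — a liability-threshold
  coupling rather than post-hoc relabelling, the simplest generative
  story consistent with a recessive odds ratio. The causal SNP's $r^2$
  is drawn on (0.8, 1): a sentinel association signal presupposes decent
  imputation.

What the generator does **not** emulate: assay plate/batch effects,
linkage disequilibrium (SNPs are independent), missing values, and any
relationship between the biotraits and the proteins. Passing tests
therefore demonstrate that the *procedures* behave as specified under
the assumed data structure, not that the biological findings would
replicate on real cohorts.

## Numerical choices and degenerate inputs

* Population variance in the standardizer; constant features flagged and
  zeroed (above).
* ENN requires an odd $k$ (vote always decided) and exactly two classes;
  nearest-neighbour ties break on the subject index.
* ADASYN apportionment uses largest-remainder rounding so the synthetic
  count is exact; all-zero difficulty weights fall back to uniform.
* Softmax is computed after subtracting the row maximum; cross-entropy
  floors probabilities at 1e-300. Training aborts on a non-finite loss.
* Gradient correctness is verified against central finite differences at
  a generic parameter point (small random biases): at zero biases a
  sample can sit exactly on the ReLU kink, where the loss is not
  differentiable and a finite-difference comparison is meaningless.
* The LIME ridge penalty defaults to 1e-6 — negligible against 5000
  weighted samples but enough to keep the normal equations
  well-conditioned; an exactly singular system with a zero penalty is
  an explicit error suggesting a positive one. Zero-variance features
  are held at the instance's value during perturbation.
* Fisher's two-sided rule uses the `(1 + 1e-7)` probability-comparison
  guard standard in exact-test implementations.
* IRLS floors the working weights at 1e-10 and reports non-convergence
  with the gradient norm; separation is detected from the data pattern
  (zero AA cell) before estimates can diverge.
* Published-style report rendering: integer percentages, "< 1%" for
  nonzero cells under 1 percent, "-" for empty cells, allele
  frequencies to 3 decimals.

## Reproducibility

Every stochastic operation takes a seed; one global seed derives each
stage's seed by hashing a stage label (`stage_seed`), so a full pipeline
run is byte-identical under a fixed seed and any stage can be re-run in
isolation. The LIME stage derives one seed per subject, so single
subjects can be re-explained without recomputing the cohort.

## Problem sizes

The packaged analyses and tests run at desk scale by design: the
analysis scripts use the full cohort composition (1388 subjects, 395
features) with 1000 SNPs and 1000 LIME perturbations per subject; the
test suite exercises the same code on cohorts of tens-to-hundreds of
subjects, 10-80 SNPs, and toy networks small enough for exhaustive
finite-difference checking. Property checks use 10-100 seeds per
invariant. These sizes are the package's choices for a reproducible
desk run; all of them are configuration, not constants.

## Known limitations

* The ENN removal rate depends strongly on class overlap: with the
  generator's default moderate effect size the synthetic DVT class is
  already homogeneous and few subjects are removed, whereas noisy real
  cohorts lose a large fraction of the majority class. The filter, not
  the removal rate, is the tested contract.
* An additive-coded scan of a rare recessive signal (effect-allele
  frequency 0.09 gives ~1% homozygotes) is underpowered at desk-scale
  cohort sizes; the planted causal SNP ranks highly but not always
  first, and the top scan hit inherits winner's-curse inflation in the
  downstream case-control tests. This mirrors the suggestive (not
  genome-wide significant) character such signals have in practice.
* The LIME surrogate's weighted $R^2$ is reported per subject and is
  typically 0.5-0.7 against this network — local linear fidelity, not a
  global account of the classifier.
* `n_iterations` defaults to 50 with iteration-level early stopping on
  the fixed monitoring split; the iterative recipe's stopping rule is
  otherwise unspecified, and this default is a design choice.
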