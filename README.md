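# pelime

Machine-learning and genetic dissection of pulmonary-embolism (PE) risk
in venous-thrombosis cohorts.

Most patients with venous thromboembolism present with deep vein
thrombosis (DVT); a minority embolize to the lung. `pelime` is for
researchers who want to mine plasma proteomics (antibody
suspension-bead-array intensities plus routine biological traits) for
molecular signals that separate isolated PE from isolated DVT, and then
follow those signals into genetics. The package provides every stage as
a tested, seeded function, plus a synthetic cohort generator with the
statistical structure the analysis assumes, so the whole workflow runs
and is verifiable without patient-level data.

## The method

1. **Homogenize.** Standardize all $p = 395$ features to zero mean/unit
   variance; discard the mixed DVT+PE class; remove DVT subjects whose
   label disagrees with the majority vote of their $k = 3$ nearest
   neighbours (edited nearest neighbours, Euclidean distance on the
   standardized vector).
2. **Balance and train.** Train a feed-forward network
   $395 \to 395 \to 128 \to 2$ (ReLU hidden layers, softmax output,
   cross-entropy loss, SGD with learning rate 0.01 and batch size 32,
   90/10 inner split with early stopping) iteratively: each iteration
   draws 30 real PE + 100 real DVT and adds 70 ADASYN-synthetic PE
   points, so every $D_i$ is a balanced 100 vs 100 set. ADASYN places
   synthetic points near the class boundary: minority point $x_i$
   receives a share of the synthetic budget proportional to
   $r_i = \Delta_i / k$ (majority fraction among its $k = 5$ nearest
   neighbours) and each synthetic point is
   $s = x_i + \lambda (x_z - x_i)$, $\lambda \sim U(0,1)$, with $x_z$ a
   minority neighbour.
3. **Explain.** For each subject, LIME fits a proximity-weighted ridge
   linear surrogate of the network's PE probability over Gaussian
   perturbations ($w_j = e^{-d_j^2/\sigma_k^2}$,
   $\sigma_k = 0.75\sqrt{p}$). The surrogate evaluated at the subject,
   clipped to $[0,1]$, is the subject's *local prediction*; collected
   cohort-wide it is the quantitative **LIME predictor**. Mean absolute
   local weights rank the globally important features.
4. **Genetics.** Scan imputed SNP dosages (MAF $> 0.01$, imputation
   $r^2 > 0.5$) for linear association with the predictor
   ($p < 5 \times 10^{-8}$ flagged genome-wide significant). For a
   candidate SNP, run case-control genetics of PE vs DVT on best-guess
   genotypes: Cochran-Armitage trend, the exact recessive test (AA vs
   GG+GA), and an age/sex-adjusted logistic fit (IRLS) that reports the
   odds ratio as *undefined* under separation instead of a diverged
   estimate.
5. **Prioritize.** Filter annotated rare variants of discordantly
   predicted patients: likely functional, in a curated VTE gene panel,
   population frequency absent or < 1‰, singleton (tier 1); genome-wide
   with CADD/SIFT/PolyPhen support only if tier 1 is empty (tier 2).

The methods vignette (`vignettes/pelime-methods.Rmd`) documents every
assumption, default and numerical choice.

## Worked example

The numbered scripts under `analysis/` run the whole study on a
synthetic cohort at the published composition (1105 DVT / 95 PE / 188
DVT+PE, 376 antibodies + 19 biotraits, 1000 SNPs with one recessive
causal variant at effect-allele frequency 0.09):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_train_ann.R
Rscript analysis/04_explain.R
Rscript analysis/05_genetics.R
Rscript analysis/06_prioritize.R
```

Output of a complete run (global seed 20260919):

```
cohort: 1388 subjects (DVT=1105, DVT_PE=188, PE=95)
ANN dataset: 1189 subjects (1094 DVT kept of 1105, all 95 PE kept)
iterations run: 21 (best monitoring loss 0.3115)
test AUC: 0.767; F1 DVT 0.83, F1 PE 0.50
test AUC: ANN 0.767 vs LIME predictor 0.800
top-20 importance contains 17 of 20 planted features
scan: 712 of 1000 SNPs pass filters
causal SNP rank by p: 6
LIME predictor by genotype:
  genotype   n       mean        sd
1       GG 303 0.05542648 0.1995800
2       GA 604 0.07423560 0.2340344
3       AA 282 0.12358365 0.2989421
shortlist: 4 variant(s), tier 1
```

Reading this: ENN removes few synthetic DVT subjects because the
generated majority class is already homogeneous; the iteratively
balanced network separates held-out PE from DVT (AUC 0.767 on the
16-subject test split); the LIME predictor tracks the network closely
(AUC 0.800) and recovers most of the planted informative proteins; the
additive-coded scan ranks the planted rare recessive SNP 6th of 712 —
the suggestive-signal regime such variants occupy in practice — and the
predictor rises with effect-allele dose at the scan's top locus (means
0.055 / 0.074 / 0.124 for GG / GA / AA); the rare-variant filter
reduces 200 annotated variants to 4 tier-1 candidates. A single call,
`run_all(pipeline_config(seed = 1), "out/")`, produces the same
artifacts programmatically.

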