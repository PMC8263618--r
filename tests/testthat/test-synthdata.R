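test_that("cohort generation is deterministic and matches the requested composition", {
  spec <- tiny_spec(seed = 7)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)

  big <- cohort_spec(n_dvt = 1105, n_pe = 95, n_dvt_pe = 188,
                     n_antibodies = 8, n_biotraits = 2, n_snps = 1,
                     n_informative_features = 2, seed = 3)
  co <- generate_cohort(big)
  expect_equal(unname(table(co$subjects$vte_class)[c("DVT", "PE", "DVT_PE")]),
               c(1105, 95, 188), ignore_attr = TRUE)
  expect_equal(dim(co$features), c(1388, 10))
  expect_false(anyNA(co$features))
  expect_true(all(co$features > 0))  # raw intensity scale
})

test_that("age and sex marginals are plausible for a VTE cohort", {
  co <- generate_cohort(tiny_spec(seed = 2, n_dvt = 400, n_pe = 200,
                                  n_dvt_pe = 0))
  s <- co$subjects
  expect_gt(mean(s$age), 40); expect_lt(mean(s$age), 55)
  expect_gt(mean(s$sex[s$vte_class == "PE"] == "F"), 0.7)
  expect_gt(mean(s$sex[s$vte_class == "DVT"] == "F"), 0.5)
})

test_that("with no planted effect, PE and DVT features are identical in law", {
  rejections <- 0L
  n_rep <- 30L
  for (s in seq_len(n_rep)) {
    co <- generate_cohort(tiny_spec(seed = 100 + s, effect_size_sd_units = 0,
                                    interaction_pairs = 0, n_dvt = 40,
                                    n_pe = 40, n_dvt_pe = 0))
    x <- co$features[co$subjects$vte_class == "DVT", 1]
    y <- co$features[co$subjects$vte_class == "PE", 1]
    if (suppressWarnings(stats::ks.test(x, y)$p.value) < 0.05)
      rejections <- rejections + 1L
  }
  expect_lte(rejections, qbinom(0.999, n_rep, 0.05))
})

test_that("planted mean shift moves informative features in PE subjects", {
  co <- generate_cohort(tiny_spec(seed = 5, n_dvt = 300, n_pe = 150,
                                  n_dvt_pe = 0, effect_size_sd_units = 1.5))
  inf <- co$meta$informative_features
  lx <- log(co$features)
  d <- colMeans(lx[co$subjects$vte_class == "PE", inf, drop = FALSE]) -
    colMeans(lx[co$subjects$vte_class == "DVT", inf, drop = FALSE])
  expect_true(all(d > 0))
})

test_that("interaction pairs carry signal in the product, not the margins", {
  co <- generate_cohort(tiny_spec(seed = 9, n_dvt = 2000, n_pe = 2000,
                                  n_dvt_pe = 0, n_informative_features = 0,
                                  interaction_pairs = 1,
                                  effect_size_sd_units = 1.5))
  pr <- co$meta$interaction_pairs[1, ]
  lx <- log(co$features)
  pe <- co$subjects$vte_class == "PE"
  # products separate the classes ...
  prod_gap <- mean(lx[pe, pr[1]] * lx[pe, pr[2]]) -
    mean(lx[!pe, pr[1]] * lx[!pe, pr[2]])
  expect_gt(prod_gap, 0)
  # ... while marginal means barely move (well under the 1.5 sd shift)
  m_gap <- abs(colMeans(lx[pe, pr, drop = FALSE]) -
                 colMeans(lx[!pe, pr, drop = FALSE]))
  sdlog <- apply(lx[!pe, pr, drop = FALSE], 2, sd)
  expect_true(all(m_gap < 0.25 * sdlog * 1.5))
})

test_that("genotypes respect Hardy-Weinberg proportions in the null model", {
  spec <- cohort_spec(n_dvt = 10000, n_pe = 0, n_dvt_pe = 0,
                      n_antibodies = 2, n_biotraits = 0, n_snps = 3,
                      causal_maf = 0.2, causal_recessive_logodds = 0,
                      n_informative_features = 0, effect_size_sd_units = 0,
                      interaction_pairs = 0, seed = 21)
  co <- generate_cohort(spec)
  ge <- generate_genotypes(co, spec)
  g <- best_guess_genotypes(ge$dosage[, ge$info$causal])
  freq <- tabulate(g + 1L, 3L) / length(g)
  expect_true(all(abs(freq - c(0.64, 0.32, 0.04)) < 0.02))
})

test_that("a null causal effect leaves AA frequency equal across classes", {
  spec <- tiny_spec(seed = 13, n_dvt = 1500, n_pe = 1500, n_dvt_pe = 0,
                    causal_maf = 0.3, causal_recessive_logodds = 0,
                    n_snps = 2)
  co <- generate_cohort(spec)
  ge <- generate_genotypes(co, spec)
  aa <- best_guess_genotypes(ge$dosage[, ge$info$causal]) == 2L
  pe <- co$subjects$vte_class == "PE"
  p <- stats::prop.test(c(sum(aa[pe]), sum(aa[!pe])),
                        c(sum(pe), sum(!pe)))$p.value
  expect_gt(p, 0.01)
})

test_that("the recessive liability effect enriches AA carriers among PE subjects", {
  hits <- vapply(1:40, function(s) {
    spec <- cohort_spec(n_dvt = 1250, n_pe = 300, n_dvt_pe = 0,
                        n_antibodies = 2, n_biotraits = 0, n_snps = 2,
                        causal_maf = 0.09,
                        causal_recessive_logodds = log(5.3),
                        n_informative_features = 0, effect_size_sd_units = 0,
                        interaction_pairs = 0, seed = s)
    co <- generate_cohort(spec)
    ge <- generate_genotypes(co, spec)
    aa <- best_guess_genotypes(ge$dosage[, ge$info$causal]) == 2
    pe <- co$subjects$vte_class == "PE"
    mean(aa[pe]) > mean(aa[!pe])
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("genotype metadata flags one causal SNP and exercises the r2 filter", {
  spec <- tiny_spec(seed = 4, n_snps = 400)
  co <- generate_cohort(spec)
  ge <- generate_genotypes(co, spec)
  expect_equal(sum(ge$info$causal), 1)
  expect_true(all(ge$dosage >= 0 & ge$dosage <= 2))
  frac_fail <- mean(ge$info$imput_r2 <= 0.5)
  expect_gt(frac_fail, 0.1); expect_lt(frac_fail, 0.5)
  expect_gt(ge$info$imput_r2[ge$info$causal], 0.5)
})

test_that("degenerate specifications are rejected", {
  expect_error(cohort_spec(causal_maf = 0), "causal_maf")
  expect_error(cohort_spec(causal_maf = 0.6), "causal_maf")
  expect_error(cohort_spec(n_pe = 0, n_informative_features = 5,
                           effect_size_sd_units = 1), "no PE subjects")
  expect_error(cohort_spec(n_antibodies = 4, n_informative_features = 10),
               "exceed")
})

test_that("annotated-variant generation is deterministic and plants survivors", {
  a <- generate_annotated_variants(n = 80, n_tier1 = 2, seed = 5)
  b <- generate_annotated_variants(n = 80, n_tier1 = 2, seed = 5)
  expect_identical(a, b)
  hits <- prioritize_variants(a)
  expect_gte(nrow(hits), 2)
  expect_true(all(hits$tier == 1))
})
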