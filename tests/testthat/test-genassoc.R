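test_that("allele frequencies reproduce the published table from its counts", {
  expect_equal(round(allele_freq(c(1028, 185, 5))$freq, 3), 0.080)
  expect_equal(round(allele_freq(c(258, 59, 7))$freq, 3), 0.113)
  expect_equal(round(allele_freq(c(149, 47, 0))$freq, 3), 0.120)
  expect_equal(round(allele_freq(c(110, 28, 5))$freq, 3), 0.133)
  expect_equal(allele_freq(c(50, 0, 0))$freq, 0)
  expect_false(allele_freq(c(0, 10, 90))$minor)  # counted allele not minor
  expect_error(allele_freq(c(0, 0, 0)), "zero")
})

test_that("best-guess genotypes round dosages with the half-up tie rule", {
  expect_identical(best_guess_genotypes(c(0.2, 1.5, 0.5, 1.49, 2)),
                   c(0L, 2L, 1L, 1L, 2L))
  g <- c(0L, 1L, 2L, 1L)
  expect_identical(best_guess_genotypes(as.numeric(g)), g)
  expect_error(best_guess_genotypes(c(0.5, 2.2)), "\\[0, 2\\]")
})

test_that("the trend test equals the score-regression chi-squared oracle", {
  # oracle: N * r^2 between per-subject genotype score and case indicator
  ca_oracle <- function(counts) {
    score <- rep(rep(c(0, 1, 2), 2),
                 c(counts$cases, counts$controls))
    case <- rep(c(1, 0), c(sum(counts$cases), sum(counts$controls)))
    length(case) * stats::cor(score, case)^2
  }
  m <- martha_counts()
  tt <- trend_test(m)
  expect_lt(abs(tt$statistic - ca_oracle(m)), 1e-9)
  expect_equal(tt$p, stats::pchisq(tt$statistic, 1, lower.tail = FALSE))

  for (s in 1:20) {
    counts <- withr::with_seed(s, genotype_counts(
      cases = rmultinom(1, 150, c(0.6, 0.3, 0.1))[, 1],
      controls = rmultinom(1, 300, c(0.7, 0.25, 0.05))[, 1]))
    expect_lt(abs(trend_test(counts)$statistic - ca_oracle(counts)), 1e-9)
  }
})

test_that("trend test handles null, extreme and degenerate tables", {
  same <- genotype_counts(c(60, 30, 10), c(120, 60, 20))
  expect_equal(trend_test(same)$statistic, 0)
  expect_equal(trend_test(same)$p, 1)

  extreme <- genotype_counts(c(0, 0, 10), c(10, 0, 0))
  expect_lt(trend_test(extreme)$p, 0.001)

  degen <- genotype_counts(c(10, 0, 0), c(20, 0, 0))
  r <- trend_test(degen)
  expect_true(r$degenerate)
  expect_equal(r$p, 1)
})

test_that("Fisher recessive reproduces the published EOVT p and the enumeration oracle", {
  ev <- fisher_recessive(eovt_counts())
  expect_equal(round(ev$p, 3), 0.013)
  expect_true(is.na(ev$or))  # zero AA controls: crude OR undefined

  sym <- fisher_recessive(genotype_counts(c(90, 5, 5), c(90, 5, 5)))
  expect_equal(sym$p, 1)
  expect_equal(sym$or, 1)

  ma <- fisher_recessive(martha_counts())
  expect_equal(ma$or, (7 * 1213) / (317 * 5), tolerance = 1e-12)
  ft <- stats::fisher.test(ma$table)
  expect_equal(ma$p, ft$p.value, tolerance = 1e-12)
})

test_that("Fisher recessive agrees with stats::fisher.test across random tables", {
  for (s in 1:25) {
    counts <- withr::with_seed(s, genotype_counts(
      cases = rmultinom(1, sample(20:200, 1), c(0.7, 0.2, 0.1))[, 1] + c(1, 0, 0),
      controls = rmultinom(1, sample(20:300, 1), c(0.8, 0.15, 0.05))[, 1] + c(1, 0, 0)))
    ours <- fisher_recessive(counts)
    expect_equal(ours$p, stats::fisher.test(ours$table)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("logistic recessive matches glm and the saturated 2x2 odds ratio", {
  # explicit 2x2: 30 AA cases, 70 non-AA cases, 10 AA controls, 90 non-AA
  case <- rep(c(1, 0), c(100, 100))
  aa <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  fit <- logistic_recessive(case, aa)
  expect_false(fit$separated)
  expect_equal(fit$or, (30 * 90) / (70 * 10), tolerance = 1e-6)

  withr::with_seed(41, {
    n <- 800
    aa2 <- rbinom(n, 1, 0.15)
    age <- rnorm(n, 50, 12)
    sex <- rbinom(n, 1, 0.6)
    case2 <- rbinom(n, 1, plogis(-1 + 1.2 * aa2 + 0.01 * age - 0.3 * sex))
  })
  ours <- logistic_recessive(case2, aa2, age, sex)
  ref <- stats::glm(case2 ~ aa2 + age + sex, family = stats::binomial())
  expect_equal(unname(ours$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(ours$se), unname(summary(ref)$coefficients[, 2]),
               tolerance = 1e-6)
})

test_that("separation is detected and reported as an undefined odds ratio", {
  # EOVT-style: no AA among controls
  case <- rep(c(1, 0), c(143, 196))
  aa <- c(rep(1, 5), rep(0, 138), rep(0, 196))
  fit <- logistic_recessive(case, aa, age = rnorm(339, 50, 10),
                            sex = rbinom(339, 1, 0.5))
  expect_true(fit$separated)
  expect_true(is.na(fit$or))
  expect_true(is.na(fit$p))
})

test_that("the quantitative scan filters on MAF and imputation quality", {
  spec <- tiny_spec(seed = 19, n_dvt = 150, n_pe = 150, n_dvt_pe = 0,
                    n_snps = 60, causal_recessive_logodds = 0)
  co <- generate_cohort(spec)
  ge <- generate_genotypes(co, spec)
  pred <- withr::with_seed(2, stats::setNames(runif(nrow(co$subjects)),
                                              co$subjects$subject_id))
  res <- quant_scan(pred, ge)
  low_r2 <- ge$info$imput_r2 <= 0.5
  expect_true(all(!res$passed_filters[low_r2]))
  expect_true(all(is.na(res$p[!res$passed_filters])))
  expect_true(all(!is.na(res$p[res$passed_filters])))
  expect_identical(res$snp_id, ge$info$snp_id)

  # slope/se/p agree with lm() on one SNP
  j <- which(res$passed_filters)[1]
  ref <- summary(stats::lm(pred ~ ge$dosage[, j]))$coefficients
  expect_equal(res$beta[j], ref[2, 1], tolerance = 1e-10)
  expect_equal(res$se[j], ref[2, 2], tolerance = 1e-10)
  expect_equal(res$p[j], ref[2, 4], tolerance = 1e-10)

  expect_error(quant_scan(unname(pred), ge), "ids")
})

test_that("the scan localizes a planted recessive signal", {
  spec <- tiny_spec(seed = 23, n_dvt = 500, n_pe = 250, n_dvt_pe = 0,
                    n_snps = 80, causal_maf = 0.25,
                    causal_recessive_logodds = log(8))
  co <- generate_cohort(spec)
  ge <- generate_genotypes(co, spec)
  # predictor proxies PE membership with noise
  pred <- withr::with_seed(5, stats::setNames(
    0.4 * (co$subjects$vte_class == "PE") + runif(750) * 0.6,
    co$subjects$subject_id))
  res <- quant_scan(pred, ge)
  causal <- which(ge$info$causal)
  expect_true(res$passed_filters[causal])
  expect_gt(res$beta[causal], 0)
  expect_equal(which.min(res$p), causal)
})

test_that("genotype-group summaries use the sample convention", {
  pred <- c(0.1, 0.2, 0.3, 0.5, 0.8, 0.9)
  g <- c(0L, 0L, 1L, 1L, 2L, 2L)
  gs <- genotype_group_stats(pred, g)
  expect_equal(gs$mean, c(0.15, 0.4, 0.85))
  expect_equal(gs$sd, c(sd(c(0.1, 0.2)), sd(c(0.3, 0.5)), sd(c(0.8, 0.9))))
  expect_identical(gs$genotype, c("GG", "GA", "AA"))

  const <- genotype_group_stats(rep(0.5, 6), g)
  expect_true(all(const$mean == 0.5) && all(const$sd == 0))
  absent <- genotype_group_stats(pred[1:4], g[1:4])
  expect_identical(absent$genotype, c("GG", "GA"))  # empty class absent
})

test_that("Spearman correlation handles monotone, tied and degenerate input", {
  expect_equal(spearman_corr(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_corr(1:10, -(1:10))$rho, -1)
  expect_equal(spearman_corr(1:10, (1:10)^3)$p, 0)

  x <- c(1, 2, 2, 4, 5); y <- c(2, 1, 4, 3, 5)
  ours <- spearman_corr(x, y)
  # brute-force midrank formula
  rx <- rank(x); ry <- rank(y)
  rho_ref <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(ours$rho, rho_ref, tolerance = 1e-12)
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
})

test_that("the association report renders counts the way the table prints them", {
  rep_m <- assoc_report(martha_counts())
  expect_identical(rep_m$table$controls,
                   c("1028 (84%)", "185 (15%)", "5 (< 1%)"))
  expect_identical(rep_m$table$cases, c("258 (80%)", "59 (18%)", "7 (2%)"))
  expect_equal(unname(rep_m$maf), c(0.080, 0.113))

  rep_e <- assoc_report(eovt_counts())
  expect_identical(rep_e$table$controls[3], "0 (-)")
  expect_identical(rep_e$table$cases[3], "5 (3%)")
})
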