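## Genetics of the LIME predictor and of PE risk: allele frequencies,
## Cochran-Armitage trend test, Fisher exact recessive test, age/sex
## adjusted logistic regression with separation detection (IRLS,
## implemented in-package), the quantitative-trait scan over dosages,
## genotype-group summaries and Spearman correlation.

#' Case-control genotype counts
#'
#' The unit of a published association table: genotype counts (GG, GA,
#' AA, with A the effect allele) among cases (PE) and controls (DVT).
#'
#' @param cases,controls numeric length-3 vectors of counts, order
#'   (GG, GA, AA).
#' @param effect_allele label of the counted allele.
#' @export
genotype_counts <- function(cases, controls, effect_allele = "A") {
  stopifnot(length(cases) == 3, length(controls) == 3,
            all(cases >= 0), all(controls >= 0),
            sum(cases) > 0, sum(controls) > 0)
  structure(list(cases = stats::setNames(as.numeric(cases), c("GG", "GA", "AA")),
                 controls = stats::setNames(as.numeric(controls), c("GG", "GA", "AA")),
                 effect_allele = effect_allele),
            class = "genotype_counts")
}

#' Effect-allele frequency from genotype counts
#'
#' `(n_GA + 2 n_AA) / (2 N)` for one group; reports are conventionally
#' given to 3 decimals. When the frequency exceeds 0.5 the counted allele
#' is not the minor one, which the `minor` flag records.
#'
#' @param counts numeric length-3 vector (GG, GA, AA).
#' @return list(freq, minor = TRUE when freq <= 0.5).
#' @export
allele_freq <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("zero genotype total", call. = FALSE)
  f <- (counts[2] + 2 * counts[3]) / (2 * n)
  list(freq = unname(f), minor = unname(f <= 0.5))
}

#' Best-guess genotypes from imputed dosages
#'
#' Nearest integer in `{0, 1, 2}`; half-way dosages (0.5, 1.5) round up,
#' a documented tie rule (ties have measure zero in imputed data).
#'
#' @param dosage numeric vector in `[0, 2]`.
#' @return Integer vector of allele counts.
#' @export
best_guess_genotypes <- function(dosage) {
  if (any(!is.finite(dosage)) || any(dosage < 0 | dosage > 2))
    stop("dosages must lie in [0, 2]", call. = FALSE)
  as.integer(floor(dosage + 0.5))
}

#' Cochran-Armitage trend test
#'
#' Tests for a linear trend in case proportion across ordered genotype
#' classes with scores (0, 1, 2) by default. The statistic equals
#' `N * r^2` where `r` is the Pearson correlation between the per-subject
#' score and the case indicator; p is from the chi-squared distribution
#' with 1 df. A table with all subjects in one genotype class is
#' degenerate: statistic 0, p 1, flagged.
#'
#' @param counts a [genotype_counts()].
#' @param scores genotype scores.
#' @return list(statistic, p, degenerate).
#' @export
trend_test <- function(counts, scores = c(0, 1, 2)) {
  stopifnot(inherits(counts, "genotype_counts"), length(scores) == 3)
  a <- counts$cases; b <- counts$controls
  ncol_tot <- a + b
  N <- sum(ncol_tot); R <- sum(a)
  s1 <- sum(scores * ncol_tot); s2 <- sum(scores^2 * ncol_tot)
  denom <- R * (N - R) * (N * s2 - s1^2)
  if (denom <= 0)
    return(list(statistic = 0, p = 1, degenerate = TRUE))
  num <- N * sum(scores * a) - R * s1
  stat <- N * num^2 / denom
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Fisher exact test under the recessive model
#'
#' Collapses the genotype table to AA vs (GG + GA) by case status and
#' computes the exact two-sided hypergeometric p as the sum of the
#' probabilities of all tables (with the observed margins) no more likely
#' than the observed one — the common two-sided convention. The crude
#' odds ratio is the cross-product ratio with a Woolf 95 percent CI; both
#' are undefined (NA) when any collapsed cell is zero.
#'
#' @param counts a [genotype_counts()].
#' @return list(p, or, ci (length 2), table (the collapsed 2x2)).
#' @export
fisher_recessive <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  a <- counts$cases["AA"];  b <- sum(counts$cases[c("GG", "GA")])
  c <- counts$controls["AA"]; d <- sum(counts$controls[c("GG", "GA")])
  tab <- matrix(c(a, b, c, d), 2, byrow = TRUE,
                dimnames = list(c("case", "control"), c("AA", "GG+GA")))
  K <- a + c          # AA margin
  R <- a + b          # case margin
  N <- a + b + c + d
  if (K + R == 0 || R == N || K == N)
    stop("empty margin in recessive 2x2", call. = FALSE)
  support <- max(0, K + R - N):min(K, R)
  pr <- stats::dhyper(support, K, N - K, R)
  p_obs <- stats::dhyper(a, K, N - K, R)
  p <- sum(pr[pr <= p_obs * (1 + 1e-7)])
  if (all(tab > 0)) {
    or <- (a * d) / (b * c)
    se_log <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    ci <- exp(log(or) + c(-1, 1) * 1.96 * se_log)
  } else {
    or <- NA_real_; ci <- c(NA_real_, NA_real_)
  }
  list(p = min(p, 1), or = unname(or), ci = unname(ci), table = tab)
}

#' Logistic regression for a recessive genetic effect, with separation
#' detection
#'
#' Maximum-likelihood logistic regression of case status on an
#' AA-homozygote indicator, optionally adjusted for age and sex, fitted
#' by iteratively reweighted least squares. When the AA column of the
#' case-by-genotype table has a zero cell (no AA controls or no AA
#' cases) the maximum-likelihood estimate diverges (complete or
#' quasi-separation); the fit is flagged and the odds ratio reported as
#' undefined instead of a diverged number.
#'
#' @param case 0/1 (or logical) case indicator.
#' @param aa 0/1 (or logical) AA-homozygote indicator.
#' @param age,sex optional covariates (`sex` coded or coercible to 0/1).
#' @param max_iter,tol IRLS controls.
#' @return list(or, ci, p, beta, se, separated, converged, n_iter).
#' @export
logistic_recessive <- function(case, aa, age = NULL, sex = NULL,
                               max_iter = 50, tol = 1e-10) {
  case <- as.numeric(case); aa <- as.numeric(aa)
  stopifnot(all(case %in% 0:1), all(aa %in% 0:1))
  if (sum(case) == 0 || sum(case) == length(case))
    stop("need at least one case and one control", call. = FALSE)
  X <- cbind(intercept = 1, aa = aa)
  if (!is.null(age)) X <- cbind(X, age = as.numeric(age))
  if (!is.null(sex)) {
    if (is.character(sex) || is.factor(sex)) sex <- as.integer(factor(sex)) - 1L
    X <- cbind(X, sex = as.numeric(sex))
  }

  separated <- sum(aa * case) == 0 || sum(aa * (1 - case)) == 0

  beta <- numeric(ncol(X))
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    score <- crossprod(X, case - mu)
    info <- crossprod(X, w * X)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  if (!converged && !separated)
    warning(sprintf("IRLS did not converge in %d iterations (gradient norm %.3g)",
                    max_iter, sqrt(sum(crossprod(X, case - stats::plogis(drop(X %*% beta)))^2))))

  se <- sqrt(diag(solve(crossprod(X, pmax(stats::plogis(drop(X %*% beta)) *
                                            (1 - stats::plogis(drop(X %*% beta))), 1e-10) * X))))
  names(se) <- colnames(X)
  names(beta) <- colnames(X)
  if (separated) {
    or <- NA_real_; ci <- c(NA_real_, NA_real_); p <- NA_real_
  } else {
    or <- exp(beta["aa"])
    ci <- exp(beta["aa"] + c(-1, 1) * 1.96 * se["aa"])
    z <- beta["aa"] / se["aa"]
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(or = unname(or), ci = unname(ci), p = unname(p),
       beta = beta, se = se, separated = separated,
       converged = converged, n_iter = it)
}

#' Quantitative-trait association scan of the LIME predictor
#'
#' Filters SNPs to minor allele frequency above `maf_min` and imputation
#' quality above `r2_min`, then regresses the predictor on the
#' effect-allele dosage per passing SNP (simple linear regression:
#' slope, its standard error, t-based p). Failing SNPs are emitted with
#' `passed_filters = FALSE` and no test. Subjects are matched by id; a
#' mismatch is an error, never a silent reindex.
#'
#' @param predictor named numeric vector (names = subject ids).
#' @param geno a `genotype_data`.
#' @param maf_min,r2_min filter thresholds (defaults 0.01 and 0.5).
#' @param gw_threshold genome-wide significance threshold (default
#'   5e-8).
#' @return data.frame(snp_id, beta, se, p, maf, imput_r2,
#'   passed_filters, genomewide).
#' @export
quant_scan <- function(predictor, geno, maf_min = 0.01, r2_min = 0.5,
                       gw_threshold = 5e-8) {
  stopifnot(inherits(geno, "genotype_data"))
  if (is.null(names(predictor)) ||
      !identical(names(predictor), rownames(geno$dosage)))
    stop("predictor subject ids do not match genotype rows", call. = FALSE)
  D <- geno$dosage
  n <- nrow(D)
  af <- colMeans(D) / 2
  maf <- pmin(af, 1 - af)
  pass <- maf > maf_min & geno$info$imput_r2 > r2_min

  beta <- se <- p <- rep(NA_real_, ncol(D))
  if (any(pass) && n > 2) {
    Dp <- D[, pass, drop = FALSE]
    yc <- predictor - mean(predictor)
    xm <- colMeans(Dp)
    Sxx <- colSums(Dp^2) - n * xm^2
    Sxy <- colSums(Dp * yc)
    b <- ifelse(Sxx > 0, Sxy / Sxx, NA_real_)
    rss <- sum(yc^2) - b^2 * Sxx
    s <- sqrt(pmax(rss, 0) / (n - 2) / Sxx)
    tval <- b / s
    beta[pass] <- b
    se[pass] <- s
    p[pass] <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  data.frame(snp_id = geno$info$snp_id, beta = beta, se = se, p = p,
             maf = unname(maf), imput_r2 = geno$info$imput_r2,
             passed_filters = unname(pass),
             genomewide = !is.na(p) & p < gw_threshold,
             stringsAsFactors = FALSE)
}

#' Predictor mean and sd per best-guess genotype class
#'
#' @param predictor numeric vector.
#' @param genotypes integer vector in `{0, 1, 2}` (effect-allele count),
#'   aligned with `predictor`.
#' @return data.frame(genotype, n, mean, sd) for the classes present;
#'   sd uses the sample (n - 1) convention.
#' @export
genotype_group_stats <- function(predictor, genotypes) {
  stopifnot(length(predictor) == length(genotypes),
            all(genotypes %in% 0:2))
  lab <- c("GG", "GA", "AA")[genotypes + 1L]
  present <- c("GG", "GA", "AA")[c("GG", "GA", "AA") %in% lab]
  out <- lapply(present, function(k) {
    v <- predictor[lab == k]
    data.frame(genotype = k, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Spearman rank correlation with midranks
#'
#' Pearson correlation of midranks; p from the t approximation with
#' n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list(rho, p, n).
#' @export
spearman_corr <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for constant input", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Published-style genotype association report
#'
#' Formats a [genotype_counts()] table the way association tables are
#' printed: counts with integer percentages ("< 1%" for nonzero cells
#' under 1 percent, "-" for empty cells), the effect-allele frequency to
#' 3 decimals, the trend and Fisher recessive tests, and — when subject
#' level data are supplied — the adjusted recessive logistic fit.
#'
#' @param counts a [genotype_counts()].
#' @return list(table (data.frame of formatted rows), maf (cases,
#'   controls), trend, fisher).
#' @export
assoc_report <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  fmt <- function(n, total) {
    if (n == 0) return(sprintf("%d (-)", n))
    pct <- 100 * n / total
    if (pct < 1) sprintf("%d (< 1%%)", n) else sprintf("%d (%.0f%%)", n, pct)
  }
  tab <- data.frame(
    genotype = c("GG", "GA", "AA"),
    controls = vapply(1:3, function(i) fmt(counts$controls[i],
                                           sum(counts$controls)), ""),
    cases = vapply(1:3, function(i) fmt(counts$cases[i],
                                        sum(counts$cases)), ""),
    stringsAsFactors = FALSE)
  list(table = tab,
       maf = c(controls = round(allele_freq(counts$controls)$freq, 3),
               cases = round(allele_freq(counts$cases)$freq, 3)),
       trend = trend_test(counts),
       fisher = fisher_recessive(counts))
}
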