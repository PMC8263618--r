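## Synthetic cohort generator: seeded VTE cohorts with the statistical
## structure the downstream analysis assumes (log-normal antibody
## intensities with correlated blocks, class-dependent shifts plus a
## nonlinear interaction signal, Hardy-Weinberg genotypes with one
## recessive causal SNP coupled to PE liability).

#' Specification of a synthetic VTE cohort
#'
#' Defaults mirror the composition of the discovery cohort: 1105 isolated
#' DVT, 95 isolated PE and 188 combined DVT+PE subjects, profiled on
#' 376 antibodies plus 19 biological traits, with a causal SNP of
#' effect-allele frequency 0.09 acting recessively on PE liability with
#' log-odds log(5.3).
#'
#' @param n_dvt,n_pe,n_dvt_pe class sizes.
#' @param n_antibodies,n_biotraits feature panel sizes (total feature
#'   dimension is their sum).
#' @param n_snps number of simulated SNPs (one of them causal).
#' @param causal_maf effect-allele frequency of the causal SNP, in (0, 0.5].
#' @param causal_recessive_logodds PE liability shift for effect-allele
#'   homozygotes at the causal SNP.
#' @param n_informative_features number of antibody features receiving a
#'   class-dependent mean shift.
#' @param effect_size_sd_units size of that shift, in units of the
#'   feature's log-scale standard deviation.
#' @param interaction_pairs number of feature pairs contributing a purely
#'   nonlinear (co-movement) PE signal with no marginal mean shift.
#' @param seed integer seed; a fixed seed gives byte-identical cohorts.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_dvt = 1105, n_pe = 95, n_dvt_pe = 188,
                        n_antibodies = 376, n_biotraits = 19,
                        n_snps = 1000,
                        causal_maf = 0.09,
                        causal_recessive_logodds = log(5.3),
                        n_informative_features = 20,
                        effect_size_sd_units = 0.5,
                        interaction_pairs = 2,
                        seed = 1) {
  spec <- list(
    n_dvt = assert_count(n_dvt, "n_dvt"),
    n_pe = assert_count(n_pe, "n_pe"),
    n_dvt_pe = assert_count(n_dvt_pe, "n_dvt_pe"),
    n_antibodies = assert_count(n_antibodies, "n_antibodies", min = 1),
    n_biotraits = assert_count(n_biotraits, "n_biotraits"),
    n_snps = assert_count(n_snps, "n_snps"),
    causal_maf = assert_fraction(causal_maf, "causal_maf", 0, 0.5,
                                 open_lo = TRUE, open_hi = FALSE),
    causal_recessive_logodds = as.double(causal_recessive_logodds),
    n_informative_features = assert_count(n_informative_features,
                                          "n_informative_features"),
    effect_size_sd_units = as.double(effect_size_sd_units),
    interaction_pairs = assert_count(interaction_pairs, "interaction_pairs"),
    seed = assert_count(seed, "seed")
  )
  if (spec$n_pe == 0 &&
      (spec$n_informative_features > 0 && spec$effect_size_sd_units != 0))
    stop("cannot plant PE feature effects in a cohort with no PE subjects",
         call. = FALSE)
  n_signal <- spec$n_informative_features + 2L * spec$interaction_pairs
  if (n_signal > spec$n_antibodies)
    stop("informative + interaction features exceed the antibody panel",
         call. = FALSE)
  class(spec) <- "cohort_spec"
  spec
}

# Table-1-style demographics: per-class age mean/sd and female fraction.
.class_demo <- list(
  DVT    = list(age_mean = 46.7, age_sd = 14.9, p_female = 0.65),
  PE     = list(age_mean = 48.6, age_sd = 15.3, p_female = 0.82),
  DVT_PE = list(age_mean = 51.6, age_sd = 17.0, p_female = 0.60)
)

#' Generate a synthetic VTE cohort
#'
#' Antibody/biotrait intensities are log-normal with block-correlated
#' log-scale noise (blocks of 10 features, within-block correlation 0.5,
#' emulating antibodies that target overlapping proteins). A random subset
#' of `n_informative_features` antibodies receives a log-scale mean shift
#' of `effect_size_sd_units` standard deviations in PE subjects (half the
#' shift in DVT+PE subjects, an intermediate phenotype); each of
#' `interaction_pairs` disjoint feature pairs receives, in PE subjects
#' only, a shared random-sign displacement that changes the pair's
#' co-movement but not either marginal mean — a purely nonlinear signal.
#' Age and sex marginals follow the published cohort description
#' (mean age about 47-52 years, 60-82 percent female by class).
#'
#' @param spec a [cohort_spec()].
#' @return A `pe_cohort`: list with `subjects` (data.frame of
#'   `subject_id`, `vte_class`, `age`, `sex`), `features` (numeric matrix,
#'   subjects by features, raw intensity scale) and `meta` (planted-signal
#'   bookkeeping: informative feature names, interaction pairs, the spec).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(stage_seed(spec$seed, "cohort"), {
    n <- spec$n_dvt + spec$n_pe + spec$n_dvt_pe
    if (n == 0L) stop("empty cohort", call. = FALSE)
    cls <- rep(c("DVT", "PE", "DVT_PE"),
               times = c(spec$n_dvt, spec$n_pe, spec$n_dvt_pe))
    ids <- sprintf("S%05d", seq_len(n))

    age <- numeric(n); sex <- character(n)
    for (k in names(.class_demo)) {
      idx <- which(cls == k); if (!length(idx)) next
      d <- .class_demo[[k]]
      age[idx] <- pmax(18, stats::rnorm(length(idx), d$age_mean, d$age_sd))
      sex[idx] <- ifelse(stats::runif(length(idx)) < d$p_female, "F", "M")
    }

    p <- spec$n_antibodies + spec$n_biotraits
    feat_names <- c(sprintf("AB_%03d", seq_len(spec$n_antibodies)),
                    if (spec$n_biotraits > 0)
                      sprintf("BIO_%02d", seq_len(spec$n_biotraits)))
    meanlog <- stats::runif(p, 5.5, 8.5)
    sdlog <- stats::runif(p, 0.3, 0.7)

    # block-correlated standard-normal log deviations
    rho <- 0.5
    block <- (seq_len(p) - 1L) %/% 10L + 1L
    u <- matrix(stats::rnorm(n * max(block)), n, max(block))
    z <- sqrt(rho) * u[, block, drop = FALSE] +
      sqrt(1 - rho) * matrix(stats::rnorm(n * p), n, p)

    # planted signals live on the antibody panel
    n_sig <- spec$n_informative_features + 2L * spec$interaction_pairs
    sig_idx <- if (n_sig > 0) sample.int(spec$n_antibodies, n_sig) else integer(0)
    inf_idx <- utils::head(sig_idx, spec$n_informative_features)
    int_idx <- utils::tail(sig_idx, 2L * spec$interaction_pairs)
    int_pairs <- if (spec$interaction_pairs > 0)
      matrix(int_idx, ncol = 2L, byrow = TRUE) else
      matrix(integer(0), ncol = 2L)

    delta <- spec$effect_size_sd_units
    if (length(inf_idx) && delta != 0) {
      z[cls == "PE", inf_idx] <- z[cls == "PE", inf_idx] + delta
      z[cls == "DVT_PE", inf_idx] <- z[cls == "DVT_PE", inf_idx] + delta / 2
    }
    if (nrow(int_pairs) && delta != 0) {
      pe_rows <- which(cls == "PE")
      for (r in seq_len(nrow(int_pairs))) {
        s <- sample(c(-1, 1), length(pe_rows), replace = TRUE) * delta
        z[pe_rows, int_pairs[r, 1]] <- z[pe_rows, int_pairs[r, 1]] + s
        z[pe_rows, int_pairs[r, 2]] <- z[pe_rows, int_pairs[r, 2]] + s
      }
    }

    features <- exp(sweep(sweep(z, 2, sdlog, "*"), 2, meanlog, "+"))
    dimnames(features) <- list(ids, feat_names)

    structure(list(
      subjects = data.frame(subject_id = ids, vte_class = cls,
                            age = round(age, 1), sex = sex,
                            stringsAsFactors = FALSE),
      features = features,
      meta = list(informative_features = feat_names[inf_idx],
                  interaction_pairs = matrix(feat_names[int_pairs],
                                             ncol = 2L),
                  spec = spec)
    ), class = "pe_cohort")
  })
}

#' @export
print.pe_cohort <- function(x, ...) {
  tab <- table(x$subjects$vte_class)
  cat("Synthetic VTE cohort:", nrow(x$subjects), "subjects (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "),",
      ncol(x$features), "features\n")
  invisible(x)
}

#' Generate imputed genotype dosages for a cohort
#'
#' Non-causal SNPs are drawn in Hardy-Weinberg proportions at allele
#' frequencies uniform on (0.05, 0.5), independent across SNPs. The causal
#' SNP is drawn conditional on clinical class under a liability model:
#' the log-odds of PE membership (PE or DVT+PE) increase by
#' `causal_recessive_logodds` for effect-allele homozygotes, so genotypes
#' are sampled from the Hardy-Weinberg prior reweighted by class
#' likelihood. Dosages are the true allele counts plus imputation noise
#' that grows as the imputation quality r2 falls; r2 is uniform on
#' (0.3, 1) for non-causal SNPs (so roughly a quarter fail the 0.5 quality
#' filter) and uniform on (0.8, 1) for the causal SNP, which a sentinel
#' association signal requires to be well imputed.
#'
#' @param cohort a `pe_cohort`.
#' @param spec the [cohort_spec()] used to generate it.
#' @return A `genotype_data`: list with `info` (data.frame of `snp_id`,
#'   `chrom`, `pos`, `ref`, `alt` (effect allele), `imput_r2`, `causal`)
#'   and `dosage` (matrix, subjects by SNPs, values in `[0, 2]` counting
#'   the effect allele).
#' @export
generate_genotypes <- function(cohort, spec) {
  stopifnot(inherits(cohort, "pe_cohort"), inherits(spec, "cohort_spec"))
  if (spec$causal_maf <= 0) stop("causal_maf must be positive", call. = FALSE)
  if (spec$n_snps < 1L) stop("need at least one SNP", call. = FALSE)
  withr::with_seed(stage_seed(spec$seed, "genotypes"), {
    n <- nrow(cohort$subjects)
    m <- spec$n_snps
    ids <- sprintf("snp%05d", seq_len(m))
    causal_j <- if (m == 1L) 1L else sample.int(m, 1L)
    af <- stats::runif(m, 0.05, 0.5)
    af[causal_j] <- spec$causal_maf
    r2 <- stats::runif(m, 0.3, 1)
    r2[causal_j] <- stats::runif(1, 0.8, 1)

    g <- matrix(stats::rbinom(n * m, 2L, rep(af, each = n)), n, m)

    # causal SNP: HW prior reweighted by P(class | genotype)
    q <- spec$causal_maf
    prior <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    is_pe <- cohort$subjects$vte_class %in% c("PE", "DVT_PE")
    alpha <- stats::qlogis(max(min(mean(is_pe), 1 - 1e-6), 1e-6))
    p_pe_g <- stats::plogis(alpha + spec$causal_recessive_logodds * c(0, 0, 1))
    w_case <- prior * p_pe_g
    w_ctrl <- prior * (1 - p_pe_g)
    g[, causal_j] <- ifelse(
      is_pe,
      sample(0:2, n, replace = TRUE, prob = w_case),
      sample(0:2, n, replace = TRUE, prob = w_ctrl))
    # (vectorised ifelse over two pre-drawn streams keeps one RNG pass)

    noise_sd <- 0.15 * (1 - r2)
    dosage <- g + matrix(stats::rnorm(n * m), n, m) *
      matrix(noise_sd, n, m, byrow = TRUE)
    dosage <- pmin(pmax(dosage, 0), 2)
    dimnames(dosage) <- list(cohort$subjects$subject_id, ids)

    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), "")
    info <- data.frame(
      snp_id = ids,
      chrom = sample(1:22, m, replace = TRUE),
      pos = sort(sample.int(5e7, m)),
      ref = ref, alt = unname(alt),
      imput_r2 = round(r2, 4),
      causal = seq_len(m) == causal_j,
      stringsAsFactors = FALSE)
    info$chrom[causal_j] <- 7L  # causal locus placed on chr 7

    structure(list(info = info, dosage = dosage), class = "genotype_data")
  })
}

#' @export
print.genotype_data <- function(x, ...) {
  cat("Genotype dosages:", nrow(x$dosage), "subjects x", ncol(x$dosage),
      "SNPs; causal:", x$info$snp_id[x$info$causal], "\n")
  invisible(x)
}

#' Generate an annotated rare-variant table
#'
#' Emulates the whole-genome-sequencing candidate table that feeds the
#' prioritization filter: a mix of functional classes, population allele
#' frequencies (some unreported), carrier counts among the sequenced
#' subset, and in-silico deleteriousness scores. `n_tier1` variants are
#' planted to satisfy the full first-tier filter (functional, unreported
#' or rare, singleton, in a known VTE gene).
#'
#' @param n number of variants.
#' @param n_tier1 number of planted first-tier survivors.
#' @param gene_list character vector of VTE-associated gene symbols.
#' @param seed integer seed.
#' @return data.frame with the columns of [prioritize_variants()].
#' @export
generate_annotated_variants <- function(n = 200, n_tier1 = 1,
                                        gene_list = vte_gene_list(),
                                        seed = 1) {
  n <- assert_count(n, "n", 1)
  n_tier1 <- assert_count(n_tier1, "n_tier1")
  stopifnot(n_tier1 <= n)
  withr::with_seed(stage_seed(seed, "variants"), {
    classes <- c("stopgain", "stoploss", "frameshift", "nonsynonymous",
                 "splicing", "synonymous", "intronic", "other")
    genes <- c(gene_list, sprintf("GENE%03d", 1:60))
    v <- data.frame(
      chrom = sample(1:22, n, replace = TRUE),
      pos = sample.int(5e7, n),
      ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      gene = sample(genes, n, replace = TRUE),
      func_class = sample(classes, n, replace = TRUE,
                          prob = c(1, 1, 2, 8, 2, 8, 15, 8)),
      pop_af = ifelse(stats::runif(n) < 0.25, NA,
                      stats::rbeta(n, 0.3, 8)),
      carrier_count = 1L + stats::rpois(n, 0.7),
      sift = round(stats::runif(n), 3),
      polyphen = round(stats::runif(n), 3),
      cadd = round(stats::runif(n, 0, 40), 2),
      stringsAsFactors = FALSE)
    if (n_tier1 > 0) {
      idx <- sample.int(n, n_tier1)
      v$func_class[idx] <- sample(c("stopgain", "frameshift", "nonsynonymous",
                                    "splicing"), n_tier1, replace = TRUE)
      v$gene[idx] <- sample(gene_list, n_tier1, replace = TRUE)
      v$pop_af[idx] <- ifelse(stats::runif(n_tier1) < 0.5, NA, 5e-5)
      v$carrier_count[idx] <- 1L
      v$cadd[idx] <- round(stats::runif(n_tier1, 20, 40), 2)
    }
    v
  })
}
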