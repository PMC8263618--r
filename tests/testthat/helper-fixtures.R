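# Shared fixtures: all built in code, sized for speed.

tiny_spec <- function(seed = 1, ...) {
  args <- list(n_dvt = 60, n_pe = 25, n_dvt_pe = 8,
               n_antibodies = 24, n_biotraits = 4, n_snps = 30,
               n_informative_features = 6, effect_size_sd_units = 1,
               interaction_pairs = 1, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(cohort_spec, args)
}

# two labelled 2-D Gaussian blobs
blob_data <- function(n_dvt = 30, n_pe = 12, sep = 2.5, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(2 * n_dvt), ncol = 2),
               matrix(rnorm(2 * n_pe, mean = sep), ncol = 2))
    rownames(X) <- sprintf("s%03d", seq_len(nrow(X)))
    list(X = X, y = rep(c("DVT", "PE"), c(n_dvt, n_pe)))
  })
}

# brute-force ENN oracle: O(n^2) pairwise scan, ties by ascending index
enn_oracle <- function(X, y, majority, k = 3) {
  n <- nrow(X)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (y[i] != majority) next
    d <- apply(X, 1, function(r) sqrt(sum((r - X[i, ])^2)))
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k)]
    if (sum(y[nb] == majority) < (k + 1) / 2) keep[i] <- FALSE
  }
  which(keep)
}

# MARTHA / EOVT genotype count tables as printed
martha_counts <- function() genotype_counts(cases = c(258, 59, 7),
                                            controls = c(1028, 185, 5))
eovt_counts <- function() genotype_counts(cases = c(110, 28, 5),
                                          controls = c(149, 47, 0))

small_pipeline_config <- function(seed = 11) {
  pipeline_config(
    seed = seed,
    cohort = cohort_spec(n_dvt = 120, n_pe = 40, n_dvt_pe = 10,
                         n_antibodies = 30, n_biotraits = 5, n_snps = 40,
                         n_informative_features = 8,
                         effect_size_sd_units = 1.2, interaction_pairs = 1),
    train = train_config(max_epochs = 15, patience = 3, n_iterations = 3,
                         iter_patience = 2, hidden_dims = c(32, 16)),
    lime = lime_config(n_perturb = 150),
    n_iter_pe = 15, n_iter_dvt = 50,
    test_n_dvt = 8, test_n_pe = 5,
    variants_n = 60, variants_tier1 = 2)
}
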