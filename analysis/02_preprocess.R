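# Stage 2 -- standardize and homogenize the classifier dataset.
#
# Drops the mixed DVT+PE class, standardizes every feature to zero mean
# and unit variance, and removes heterogeneous DVT subjects by edited
# nearest neighbours (k = 3) on the standardized 395-feature vectors.

source("analysis/00_config.R")

cohort <- cache("cohort", generate_cohort(study_spec))

prep <- cache("prep", {
  keep2 <- cohort$subjects$vte_class %in% c("DVT", "PE")
  X_raw <- cohort$features[keep2, , drop = FALSE]
  y <- cohort$subjects$vte_class[keep2]
  scaling <- fit_standardizer(X_raw)
  Xs <- apply_standardizer(X_raw, scaling)
  kept <- enn_filter(Xs, y, majority_class = "DVT", k = 3)
  list(X = Xs[kept, , drop = FALSE], y = y[kept], scaling = scaling,
       subject_id = rownames(Xs)[kept],
       n_before = length(y), n_dvt_before = sum(y == "DVT"))
})

writeLines(prep$subject_id, file.path(paths$tables, "ann_dataset_ids.txt"))
cat(sprintf("ENN input: %d subjects (%d DVT, %d PE)\n", prep$n_before,
            prep$n_dvt_before, prep$n_before - prep$n_dvt_before))
cat(sprintf("ANN dataset: %d subjects (%d DVT kept of %d, all %d PE kept)\n",
            length(prep$y), sum(prep$y == "DVT"), prep$n_dvt_before,
            sum(prep$y == "PE")))
cat(sprintf("constant features mapped to zero: %d\n",
            sum(prep$scaling$constant)))
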