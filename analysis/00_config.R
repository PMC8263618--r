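# Shared configuration for the analysis scripts 01-06.
#
# One global seed drives every stage; intermediate objects are cached
# under scratch/ (disposable), tables land under results/.

library(pelime)

GLOBAL_SEED <- 20260919

paths <- list(
  data = "results/data",
  tables = "results",
  cache = "scratch/analysis-cache"
)
for (p in paths) dir.create(p, showWarnings = FALSE, recursive = TRUE)

# Study-scale synthetic cohort: class sizes and feature panel mirror the
# discovery study (1105 DVT / 95 PE / 188 DVT+PE; 376 antibodies + 19
# biological traits); 1000 SNPs with one recessive causal variant at
# effect-allele frequency 0.09 and liability log-odds ln(5.3).
study_spec <- cohort_spec(seed = GLOBAL_SEED)

train_cfg <- train_config(n_iterations = 30, max_epochs = 20, patience = 4,
                          iter_patience = 8, seed = GLOBAL_SEED)
adasyn_cfg <- adasyn_config(seed = GLOBAL_SEED)
lime_cfg <- lime_config(n_perturb = 1000, seed = GLOBAL_SEED)

cache <- function(name, expr) {
  path <- file.path(paths$cache, paste0(name, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  val <- expr
  saveRDS(val, path)
  val
}
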