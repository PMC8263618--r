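# Stage 4 -- LIME: local surrogates, the quantitative PE predictor, and
# global feature importance.
#
# Each subject's local linear surrogate of the trained network is
# evaluated at the subject itself; that scalar (clipped to [0,1]) is the
# LIME predictor used as the GWAS phenotype in stage 5.

source("analysis/00_config.R")

prep <- cache("prep", stop("run analysis/02_preprocess.R first"))
split <- cache("split", stop("run analysis/03_train_ann.R first"))
fit <- cache("fit", stop("run analysis/03_train_ann.R first"))

blackbox <- function(M) nn_forward(fit$params, M)[, "PE"]
predictor <- cache("predictor", cohort_predictor(blackbox, prep$X, lime_cfg))

utils::write.table(
  data.frame(subject_id = prep$subject_id,
             lime_pred = round(as.numeric(predictor), 6)),
  file.path(paths$tables, "lime_predictor.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

imp <- rank_global_importance(attr(predictor, "explanations"), top_k = 20)
utils::write.csv(imp, file.path(paths$tables, "lime_importance_top20.csv"),
                 row.names = FALSE)

ann_auc <- evaluate(fit$params, prep$X[split$test, ], prep$y[split$test])$auc
lime_auc <- evaluate(NULL, NULL, prep$y[split$test],
                     scores = as.numeric(predictor)[split$test])$auc
r2s <- vapply(attr(predictor, "explanations"), `[[`, 0, "r2")
cat(sprintf("predictor range: [%.3f, %.3f]; mean PE %.3f vs DVT %.3f\n",
            min(predictor), max(predictor),
            mean(predictor[prep$y == "PE"]),
            mean(predictor[prep$y == "DVT"])))
cat(sprintf("test AUC: ANN %.3f vs LIME predictor %.3f\n", ann_auc, lime_auc))
cat(sprintf("surrogate weighted R2: median %.3f (min %.3f)\n",
            stats::median(r2s), min(r2s)))
truly <- cache("cohort", stop("run analysis/01_simulate.R first"))$meta$informative_features
cat(sprintf("top-20 importance contains %d of %d planted features\n",
            sum(imp$feature %in% truly), length(truly)))

# per-individual test-set report: observed class vs ANN and LIME outputs
tab <- report_predictions(fit$params, predictor, prep, split$test)
utils::write.table(tab, file.path(paths$tables, "test_predictions.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("test-set discordant predictions: %d of %d\n",
            sum(tab$discordant), nrow(tab)))
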