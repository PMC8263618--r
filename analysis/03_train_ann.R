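# Stage 3 -- train the PE/DVT classifier.
#
# Holds out a small test set (10 DVT, 6 PE), then trains the
# 395-395-128-2 network by iterative balanced resampling: each iteration
# draws 30 real PE + 100 real DVT and adds 70 ADASYN-synthetic PE before
# continuing SGD (lr 0.01, batch 32, 90/10 inner split, early stopping).

source("analysis/00_config.R")

prep <- cache("prep", stop("run analysis/02_preprocess.R first"))

split <- cache("split", withr::with_seed(stage_seed(GLOBAL_SEED, "split"), {
  test_idx <- c(sample(which(prep$y == "DVT"), 10),
                sample(which(prep$y == "PE"), 6))
  list(test = sort(test_idx), train = setdiff(seq_along(prep$y), test_idx))
}))

fit <- cache("fit", iterative_train(prep$X[split$train, ], prep$y[split$train],
                                    cfg = train_cfg, adasyn_cfg = adasyn_cfg))

utils::write.csv(fit$history, file.path(paths$tables, "training_history.csv"),
                 row.names = FALSE)

train_m <- evaluate(fit$params, prep$X[split$train, ], prep$y[split$train])
test_m <- evaluate(fit$params, prep$X[split$test, ], prep$y[split$test])
cat(sprintf("iterations run: %d (best monitoring loss %.4f)\n",
            nrow(fit$history), min(fit$history$monitor_loss)))
cat(sprintf("training-pool AUC: %.3f\n", train_m$auc))
cat(sprintf("test AUC: %.3f; F1 DVT %.2f, F1 PE %.2f\n",
            test_m$auc, test_m$f1[["DVT"]], test_m$f1[["PE"]]))
print(test_m$confusion)
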