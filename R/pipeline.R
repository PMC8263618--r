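## Orchestration: the full workflow from synthetic cohort to variant
## shortlist, with one global seed, per-stage derived seeds, config
## stamping and a plain-text run log.

#' Assemble a pipeline configuration
#'
#' One global `seed` deterministically derives every stage's seed (via
#' [stage_seed()]), so a full run is reproducible and any stage can be
#' re-run in isolation. Components may be overridden individually.
#'
#' @param seed global integer seed.
#' @param cohort a [cohort_spec()] (its own seed is replaced by a derived
#'   one).
#' @param enn_k ENN neighbour count.
#' @param train a [train_config()].
#' @param adasyn an [adasyn_config()].
#' @param lime a [lime_config()].
#' @param n_iter_pe,n_iter_dvt real subjects drawn per training
#'   iteration.
#' @param test_n_dvt,test_n_pe held-out test subjects per class.
#' @param scan_maf_min,scan_r2_min scan filters.
#' @param variants_n,variants_tier1 synthetic annotated-variant table
#'   size and planted first-tier survivors.
#' @export
pipeline_config <- function(seed = 1,
                            cohort = cohort_spec(),
                            enn_k = 3,
                            train = train_config(),
                            adasyn = adasyn_config(),
                            lime = lime_config(n_perturb = 1000),
                            n_iter_pe = 30, n_iter_dvt = 100,
                            test_n_dvt = 10, test_n_pe = 6,
                            scan_maf_min = 0.01, scan_r2_min = 0.5,
                            variants_n = 200, variants_tier1 = 1) {
  seed <- assert_count(seed, "seed")
  cohort$seed <- stage_seed(seed, "cohort_stage")
  train$seed <- stage_seed(seed, "train_stage")
  adasyn$seed <- stage_seed(seed, "adasyn_stage")
  lime$seed <- stage_seed(seed, "lime_stage")
  structure(list(seed = seed, cohort = cohort, enn_k = enn_k,
                 train = train, adasyn = adasyn, lime = lime,
                 n_iter_pe = n_iter_pe, n_iter_dvt = n_iter_dvt,
                 test_n_dvt = test_n_dvt, test_n_pe = test_n_pe,
                 scan_maf_min = scan_maf_min, scan_r2_min = scan_r2_min,
                 variants_n = variants_n, variants_tier1 = variants_tier1),
            class = "pipeline_config")
}

# stamped, deterministic TSV/CSV writer
.write_artifact <- function(df, path, stamp, sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stamp, con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis workflow
#'
#' Stages, in order: simulate cohort + genotypes + annotated variants;
#' standardize features (fit on the DVT/PE subjects, DVT+PE discarded);
#' ENN-filter the DVT majority; split off a held-out test set; train the
#' classifier by iterative balanced resampling; evaluate; derive the
#' per-subject LIME predictor and global feature importances; scan the
#' genotypes for association with the predictor; run the case-control
#' recessive genetics of the top scan hit; prioritize rare variants.
#' Every table artifact is stamped with the config hash and seed, so a
#' re-run with the same configuration is byte-identical (the run log
#' carries wall times and is exempt).
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory for artifacts.
#' @return Invisibly, a list with every intermediate object and the
#'   artifact paths.
#' @export
run_all <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# pelime run: config=%s seed=%d",
                   obj_hash(config), config$seed)
  log_path <- file.path(outdir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  t0 <- Sys.time()
  logf <- function(fmt, ...) {
    writeLines(sprintf("[%6.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                       sprintf(fmt, ...)), log_con)
  }
  fail <- function(stage, e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)

  ## -- simulate ------------------------------------------------------
  sim <- tryCatch({
    cohort <- generate_cohort(config$cohort)
    geno <- generate_genotypes(cohort, config$cohort)
    variants <- generate_annotated_variants(
      n = config$variants_n, n_tier1 = config$variants_tier1,
      seed = stage_seed(config$seed, "variants_stage"))
    list(cohort = cohort, geno = geno, variants = variants)
  }, error = function(e) fail("simulate", e))
  logf("simulate: %d subjects, %d SNPs, %d variants",
       nrow(sim$cohort$subjects), ncol(sim$geno$dosage), nrow(sim$variants))

  ## -- standardize + ENN --------------------------------------------
  prep <- tryCatch({
    keep2 <- sim$cohort$subjects$vte_class %in% c("DVT", "PE")
    X_raw <- sim$cohort$features[keep2, , drop = FALSE]
    y <- sim$cohort$subjects$vte_class[keep2]
    sc <- fit_standardizer(X_raw)
    Xs <- apply_standardizer(X_raw, sc)
    kept <- enn_filter(Xs, y, majority_class = "DVT", k = config$enn_k)
    list(X = Xs[kept, , drop = FALSE], y = y[kept], scaling = sc,
         subject_id = rownames(Xs)[kept])
  }, error = function(e) fail("preprocess", e))
  logf("preprocess: ENN kept %d of %d (%d DVT, %d PE)",
       length(prep$y), sum(sim$cohort$subjects$vte_class %in% c("DVT", "PE")),
       sum(prep$y == "DVT"), sum(prep$y == "PE"))

  ## -- train/test split ---------------------------------------------
  split <- tryCatch(withr::with_seed(stage_seed(config$seed, "split"), {
    test_idx <- c(sample(which(prep$y == "DVT"), config$test_n_dvt),
                  sample(which(prep$y == "PE"), config$test_n_pe))
    list(test = sort(test_idx), train = setdiff(seq_along(prep$y), test_idx))
  }), error = function(e) fail("split", e))

  ## -- iterative ANN -------------------------------------------------
  fit <- tryCatch(
    iterative_train(prep$X[split$train, , drop = FALSE],
                    prep$y[split$train],
                    cfg = config$train, adasyn_cfg = config$adasyn,
                    n_pe = config$n_iter_pe, n_dvt = config$n_iter_dvt),
    error = function(e) fail("train", e))
  test_metrics <- evaluate(fit$params, prep$X[split$test, , drop = FALSE],
                           prep$y[split$test])
  logf("train: %d iterations, test AUC %.3f",
       nrow(fit$history), test_metrics$auc)

  ## -- LIME predictor ------------------------------------------------
  blackbox <- function(M) nn_forward(fit$params, M)[, "PE"]
  predictor <- tryCatch(cohort_predictor(blackbox, prep$X, config$lime),
                        error = function(e) fail("explain", e))
  importance <- rank_global_importance(attr(predictor, "explanations"))
  lime_test <- evaluate(NULL, NULL, prep$y[split$test],
                        scores = as.numeric(predictor)[split$test])
  logf("explain: predictor in [%.3f, %.3f], LIME test AUC %.3f",
       min(predictor), max(predictor), lime_test$auc)

  ## -- GWAS scan -----------------------------------------------------
  scan <- tryCatch({
    dos <- sim$geno$dosage[prep$subject_id, , drop = FALSE]
    g <- sim$geno; g$dosage <- dos
    pred <- stats::setNames(as.numeric(predictor), prep$subject_id)
    quant_scan(pred, g, maf_min = config$scan_maf_min,
               r2_min = config$scan_r2_min)
  }, error = function(e) fail("scan", e))
  top <- scan[scan$passed_filters, ]
  top <- top[order(top$p), ][1, ]
  logf("scan: %d/%d SNPs pass filters, top hit %s (p = %.3g)",
       sum(scan$passed_filters), nrow(scan), top$snp_id, top$p)

  ## -- case-control genetics of the top hit -------------------------
  assoc <- tryCatch({
    j <- match(top$snp_id, sim$geno$info$snp_id)
    bg <- best_guess_genotypes(sim$geno$dosage[, j])
    cls <- sim$cohort$subjects$vte_class
    cc <- cls != "DVT_PE"
    case <- as.integer(cls[cc] == "PE")
    counts <- genotype_counts(
      cases = tabulate(bg[cc][case == 1] + 1L, 3L),
      controls = tabulate(bg[cc][case == 0] + 1L, 3L))
    logit <- logistic_recessive(case, as.integer(bg[cc] == 2L),
                                age = sim$cohort$subjects$age[cc],
                                sex = sim$cohort$subjects$sex[cc])
    pred_all <- stats::setNames(as.numeric(predictor), prep$subject_id)
    gs <- genotype_group_stats(pred_all, bg[match(prep$subject_id,
                                                  sim$cohort$subjects$subject_id)])
    list(snp = top$snp_id, counts = counts, report = assoc_report(counts),
         logistic = logit, group_stats = gs)
  }, error = function(e) fail("assoc", e))
  logf("assoc: trend p %.3g, Fisher recessive p %.3g, logistic OR %s",
       assoc$report$trend$p, assoc$report$fisher$p,
       if (assoc$logistic$separated) "undefined (separation)" else
         sprintf("%.2f", assoc$logistic$or))

  ## -- rare-variant prioritization ----------------------------------
  shortlist <- tryCatch(prioritize_variants(sim$variants),
                        error = function(e) fail("prioritize", e))
  logf("prioritize: %d candidate(s), tier %s", nrow(shortlist),
       paste(unique(shortlist$tier), collapse = ","))

  ## -- artifacts -----------------------------------------------------
  paths <- list(
    predictor = .write_artifact(
      data.frame(subject_id = prep$subject_id,
                 lime_pred = sprintf("%.10g", as.numeric(predictor))),
      file.path(outdir, "predictor.tsv"), stamp),
    scan = .write_artifact(
      within(scan, { beta <- sprintf("%.10g", beta)
                     se <- sprintf("%.10g", se)
                     p <- sprintf("%.10g", p) }),
      file.path(outdir, "scan.tsv"), stamp),
    importance = .write_artifact(importance,
                                 file.path(outdir, "importance.csv"),
                                 stamp, sep = ","),
    assoc = .write_artifact(assoc$report$table,
                            file.path(outdir, "assoc_report.tsv"), stamp),
    predictions = .write_artifact(
      report_predictions(fit$params, predictor, prep, split$test),
      file.path(outdir, "predictions.tsv"), stamp),
    prioritized = .write_artifact(shortlist,
                                  file.path(outdir, "prioritized.tsv"),
                                  stamp),
    metrics = local({
      path <- file.path(outdir, "metrics.json")
      jsonlite::write_json(list(
        config_hash = obj_hash(config), seed = config$seed,
        n_ann_dataset = length(prep$y),
        n_train = length(split$train), n_test = length(split$test),
        test_auc = test_metrics$auc,
        test_f1 = as.list(test_metrics$f1),
        lime_test_auc = lime_test$auc,
        top_snp = top$snp_id, top_snp_p = top$p,
        trend_p = assoc$report$trend$p,
        fisher_p = assoc$report$fisher$p,
        logistic_or = if (assoc$logistic$separated) "Undefined" else
          assoc$logistic$or,
        n_prioritized = nrow(shortlist)),
        path, auto_unbox = TRUE, digits = NA, null = "null")
      path
    }),
    log = log_path)
  logf("done")

  invisible(list(config = config, cohort = sim$cohort, geno = sim$geno,
                 variants = sim$variants, prep = prep, split = split,
                 fit = fit, test_metrics = test_metrics,
                 predictor = predictor, importance = importance,
                 scan = scan, assoc = assoc, shortlist = shortlist,
                 paths = paths))
}

#' Per-individual prediction table for the test set
#'
#' One row per held-out subject: observed class, the classifier's PE
#' probability, the LIME local prediction, and a discordance flag set
#' when the predicted class (0.5 threshold) differs from the observed
#' one.
#'
#' @param params trained `network_params`.
#' @param predictor cohort LIME predictor (aligned with `prep$X` rows).
#' @param prep list with standardized `X` and labels `y`.
#' @param test_idx row indices of the test subjects.
#' @return data.frame(individual, observed, ann_pred_pe,
#'   lime_local_pred, discordant).
#' @export
report_predictions <- function(params, predictor, prep, test_idx) {
  p_ann <- nn_forward(params, prep$X[test_idx, , drop = FALSE])[, "PE"]
  obs <- prep$y[test_idx]
  data.frame(
    individual = prep$subject_id[test_idx],
    observed = obs,
    ann_pred_pe = sprintf("%.4f", p_ann),
    lime_local_pred = sprintf("%.4f", as.numeric(predictor)[test_idx]),
    discordant = ifelse(p_ann >= 0.5, "PE", "DVT") != obs,
    stringsAsFactors = FALSE)
}
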