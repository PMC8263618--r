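# Stage 5 -- genetics of the LIME predictor and of PE risk.
#
# Scans all imputed SNPs (MAF > 0.01, imputation r2 > 0.5) for
# association with the predictor, then takes the top hit into
# case-control genetics: Cochran-Armitage trend on best-guess genotypes,
# Fisher exact under the recessive model, age/sex-adjusted logistic
# regression with separation detection, and predictor means by genotype.

source("analysis/00_config.R")

cohort <- cache("cohort", stop("run analysis/01_simulate.R first"))
geno <- cache("geno", stop("run analysis/01_simulate.R first"))
prep <- cache("prep", stop("run analysis/02_preprocess.R first"))
predictor <- cache("predictor", stop("run analysis/04_explain.R first"))

pred <- stats::setNames(as.numeric(predictor), prep$subject_id)
g_sub <- geno
g_sub$dosage <- geno$dosage[prep$subject_id, , drop = FALSE]
scan <- quant_scan(pred, g_sub)
utils::write.table(scan, file.path(paths$tables, "predictor_gwas.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

passing <- scan[scan$passed_filters, ]
top <- passing[order(passing$p), ][1, ]
causal_id <- geno$info$snp_id[geno$info$causal]
cat(sprintf("scan: %d of %d SNPs pass filters\n", nrow(passing), nrow(scan)))
cat(sprintf("top hit: %s, beta %+.3f +/- %.3f, p = %.3g (planted causal: %s)\n",
            top$snp_id, top$beta, top$se, top$p, causal_id))
cat(sprintf("causal SNP rank by p: %d\n",
            which(passing$snp_id[order(passing$p)] == causal_id)))

# case-control genetics of the top hit, PE vs DVT, whole cohort
j <- match(top$snp_id, geno$info$snp_id)
bg <- best_guess_genotypes(geno$dosage[, j])
cc <- cohort$subjects$vte_class != "DVT_PE"
case <- as.integer(cohort$subjects$vte_class[cc] == "PE")
counts <- genotype_counts(cases = tabulate(bg[cc][case == 1] + 1L, 3L),
                          controls = tabulate(bg[cc][case == 0] + 1L, 3L))
rep <- assoc_report(counts)
print(rep$table)
cat(sprintf("MAF: DVT %.3f, PE %.3f\n", rep$maf[["controls"]],
            rep$maf[["cases"]]))
cat(sprintf("trend test: chi2 %.2f, p = %.3g\n", rep$trend$statistic,
            rep$trend$p))
cat(sprintf("Fisher recessive: p = %.3g, crude OR %s\n", rep$fisher$p,
            ifelse(is.na(rep$fisher$or), "undefined",
                   sprintf("%.2f", rep$fisher$or))))
logit <- logistic_recessive(case, as.integer(bg[cc] == 2L),
                            age = cohort$subjects$age[cc],
                            sex = cohort$subjects$sex[cc])
cat(sprintf("adjusted recessive OR: %s\n",
            if (logit$separated) "Undefined (separation)" else
              sprintf("%.2f [%.2f-%.2f], p = %.3g", logit$or,
                      logit$ci[1], logit$ci[2], logit$p)))

gs <- genotype_group_stats(pred, bg[match(prep$subject_id,
                                          cohort$subjects$subject_id)])
utils::write.table(gs, file.path(paths$tables, "predictor_by_genotype.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("LIME predictor by genotype:\n"); print(gs)

# predictor vs a biological trait (illustrative correlation)
bio1 <- cohort$features[prep$subject_id, grep("^BIO_", colnames(cohort$features))[1]]
sp <- spearman_corr(pred, bio1)
cat(sprintf("Spearman with %s: rho %.3f, p = %.3g\n",
            grep("^BIO_", colnames(cohort$features), value = TRUE)[1],
            sp$rho, sp$p))
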