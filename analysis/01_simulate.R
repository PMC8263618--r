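# Stage 1 -- simulate the synthetic VTE cohort.
#
# Generates the phenotype/feature tables, imputed genotype dosages (VCF
# and dosage-TSV dialects) and the annotated rare-variant table that the
# downstream stages consume.

source("analysis/00_config.R")

cohort <- cache("cohort", generate_cohort(study_spec))
geno <- cache("geno", generate_genotypes(cohort, study_spec))
variants <- cache("variants", generate_annotated_variants(
  n = 200, n_tier1 = 1, seed = stage_seed(GLOBAL_SEED, "variants")))

write_cohort(cohort, paths$data)
write_genotypes(geno, file.path(paths$data, "genotypes.vcf"))
write_genotypes(geno, file.path(paths$data, "genotypes.tsv"))
write_variants(variants, file.path(paths$data, "variants.tsv"))

tab <- table(cohort$subjects$vte_class)
cat(sprintf("cohort: %d subjects (%s)\n", nrow(cohort$subjects),
            paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
cat(sprintf("features: %d (%d antibodies + %d biotraits), all positive: %s\n",
            ncol(cohort$features), study_spec$n_antibodies,
            study_spec$n_biotraits, all(cohort$features > 0)))
cat(sprintf("genotypes: %d SNPs; causal %s (effect-allele freq %.3f, r2 %.2f)\n",
            ncol(geno$dosage), geno$info$snp_id[geno$info$causal],
            mean(geno$dosage[, geno$info$causal]) / 2,
            geno$info$imput_r2[geno$info$causal]))
cat(sprintf("variant table: %d rows written to %s\n", nrow(variants),
            file.path(paths$data, "variants.tsv")))
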