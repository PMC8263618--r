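# Stage 6 -- rare-variant prioritization.
#
# Applies the staged filter to the annotated variant table: likely
# functional, unreported or below 1 per mille, singleton, in a known VTE
# gene (tier 1); widened to all coding genes with deleteriousness
# support only if tier 1 comes up empty.

source("analysis/00_config.R")

variants <- read_variants(file.path(paths$data, "variants.tsv"))
shortlist <- prioritize_variants(variants)
write_variants(shortlist, file.path(paths$tables, "prioritized_variants.tsv"))

cat(sprintf("annotated variants in: %d\n", nrow(variants)))
cat(sprintf("shortlist: %d variant(s), tier %s\n", nrow(shortlist),
            paste(unique(shortlist$tier), collapse = ",")))
print(shortlist[, c("tier", "gene", "func_class", "pop_af",
                    "carrier_count", "cadd")])
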